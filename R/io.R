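# Delimited-text readers and writers.  Every writer prepends a comment
# header ("# ...") recording the producing command and seed; readers skip
# comment lines.  Comma is the default separator; tabs are accepted on read.

.pq_header <- function(command = "polyqtl", seed = NA) {
  c(sprintf("# produced by: %s", command),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# polyqtl version: %s",
            as.character(utils::packageVersion("polyqtl"))))
}

.write_table <- function(df, path, command = "polyqtl", seed = NA) {
  writeLines(.pq_header(command, seed), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

.read_table <- function(path) {
  head <- readLines(path, n = 50L)
  skip <- 0L
  while (skip < length(head) && startsWith(head[skip + 1L], "#"))
    skip <- skip + 1L
  as.data.frame(data.table::fread(path, skip = skip, header = TRUE,
                                  sep = "auto"))
}

#' Read a genetic map file
#'
#' Expects columns `marker`, `chromosome`, `position_cM` (comma- or
#' tab-separated; `#` comment lines are skipped).
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  df <- .read_table(path)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  genetic_map(df$marker, df$chromosome, df$position_cM)
}

#' Write a genetic map file
#' @param map a [genetic_map()].
#' @param path file path.
#' @param command,seed provenance recorded in the comment header.
#' @export
write_map <- function(map, path, command = "polyqtl", seed = NA) {
  .write_table(as.data.frame(map), path, command, seed)
}

#' Write a phased population
#'
#' Long format: one row per (individual, marker) with `hom1..homP` columns
#' carrying `state:founder_label` tokens (state `A`/`B`).
#'
#' @param pop a phased population.
#' @param path file path.
#' @inheritParams write_map
#' @export
write_phased <- function(pop, path, command = "polyqtl", seed = NA) {
  L <- pop$labels
  S <- snp_states(pop)
  ploidy <- pop$ploidy
  m <- ncol(L); n <- nrow(L) / ploidy
  tok <- matrix(paste0(c("A", "B")[S + 1L], ":", L), nrow = nrow(L))
  df <- data.frame(individual = rep(pop$individual, each = m),
                   marker = rep(pop$map$marker, n),
                   stringsAsFactors = FALSE)
  for (h in seq_len(ploidy))
    df[[paste0("hom", h)]] <- as.vector(t(tok[seq(h, nrow(L), by = ploidy), ,
                                              drop = FALSE]))
  .write_table(df, path, command, seed)
}

#' Read a phased population
#'
#' Inverse of [write_phased()]; rebuilds the founder-haplotype lookup from
#' the tokens and validates that each founder label always carries one SNP
#' state per marker.
#'
#' @param path file path.
#' @param map the [genetic_map()] the file refers to.
#' @return A `phased_pop` usable by the encoders ([snp_dosages()],
#'   [ibd_loci()], [build_haploblocks()]).
#' @export
read_phased <- function(path, map) {
  df <- .read_table(path)
  hom_cols <- grep("^hom", names(df), value = TRUE)
  ploidy <- length(hom_cols)
  if (ploidy < 2) stop("phased file needs hom1..homP columns")
  inds <- unique(df$individual)
  n <- length(inds); m <- nrow(map)
  if (nrow(df) != n * m)
    stop("phased file: expected ", n * m, " rows, found ", nrow(df))
  ord <- order(match(df$individual, inds), match(df$marker, map$marker))
  df <- df[ord, ]
  bad <- which(is.na(match(df$marker, map$marker)))
  if (length(bad))
    stop("phased file row ", bad[1], ": unknown marker ", df$marker[bad[1]])
  L <- matrix(0L, nrow = n * ploidy, ncol = m)
  S <- matrix(0L, nrow = n * ploidy, ncol = m)
  for (h in seq_len(ploidy)) {
    tok <- df[[hom_cols[h]]]
    parts <- regmatches(tok, regexec("^([AB]):([0-9]+)$", tok))
    ok <- lengths(parts) == 3L
    if (!all(ok))
      stop("phased file row ", which(!ok)[1], ": bad token '",
           tok[which(!ok)[1]], "'")
    st <- vapply(parts, `[`, character(1), 2)
    lb <- as.integer(vapply(parts, `[`, character(1), 3))
    rows <- seq(h, n * ploidy, by = ploidy)
    S[rows, ] <- matrix(as.integer(st == "B"), nrow = n, byrow = TRUE)
    L[rows, ] <- matrix(lb, nrow = n, byrow = TRUE)
  }
  max_label <- max(L)
  lookup <- matrix(NA_integer_, max_label, m)
  idx <- cbind(as.vector(L), rep(seq_len(m), each = nrow(L)))
  lookup[idx] <- as.vector(S)
  # last write wins above; a conflicting duplicate leaves some mismatch
  if (any(lookup[idx] != as.vector(S)))
    stop("phased file: founder label carries inconsistent SNP states")
  structure(list(labels = L, states_lookup = lookup, individual = inds,
                 family = rep(NA_integer_, n), n_ind = n, ploidy = ploidy,
                 map = map, label_ag = rep(NA_integer_, max_label)),
            class = c("phased_pop"))
}

#' Write / read a dosage matrix
#'
#' Individuals x markers integer dosages in `0..ploidy`, first column
#' `individual`.
#'
#' @param D integer dosage matrix with individual rownames.
#' @param path file path.
#' @inheritParams write_map
#' @export
write_dosage <- function(D, path, command = "polyqtl", seed = NA) {
  df <- data.frame(individual = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_table(df, path, command, seed)
}

#' @rdname write_dosage
#' @param ploidy used to validate the dosage bounds.
#' @export
read_dosage <- function(path, ploidy = 4) {
  df <- .read_table(path)
  if (names(df)[1] != "individual") stop("dosage file: first column must be 'individual'")
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "integer"
  rownames(D) <- df$individual
  bad <- which(rowSums(D < 0 | D > ploidy | is.na(D)) > 0)
  if (length(bad))
    stop("dosage file row ", bad[1], " (individual ", df$individual[bad[1]],
         "): dosage outside [0, ", ploidy, "]")
  D
}

#' Write / read a phenotype file
#'
#' Two columns: `individual`, `value`.
#'
#' @param y named numeric vector.
#' @param path file path.
#' @inheritParams write_map
#' @export
write_phenotype <- function(y, path, command = "polyqtl", seed = NA) {
  .write_table(data.frame(individual = names(y), value = unname(y),
                          stringsAsFactors = FALSE), path, command, seed)
}

#' @rdname write_phenotype
#' @param individuals optional ids that must all be present (completeness
#'   check; the design assumes complete data).
#' @export
read_phenotype <- function(path, individuals = NULL) {
  df <- .read_table(path)
  if (!all(c("individual", "value") %in% names(df)))
    stop("phenotype file must have columns individual, value")
  y <- as.numeric(df$value)
  names(y) <- df$individual
  if (any(!is.finite(y)))
    stop("phenotype file row ", which(!is.finite(y))[1], ": non-finite value")
  if (!is.null(individuals)) {
    miss <- setdiff(individuals, names(y))
    if (length(miss))
      stop("missing phenotype for individual(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    y <- y[individuals]
  }
  y
}

#' Write / read a genome scan
#' @param scan a `qtl_scan`.
#' @param path file path.
#' @inheritParams write_map
#' @export
write_scan <- function(scan, path, command = "polyqtl", seed = NA) {
  .write_table(as.data.frame(scan), path, command, seed)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- .read_table(path)
  need <- c("locus", "chromosome", "position_cM", "neglog10p", "model")
  if (!all(need %in% names(df)))
    stop("scan file must have columns: ", paste(need, collapse = ", "))
  df$chromosome <- as.character(df$chromosome)
  class(df) <- c("qtl_scan", "data.frame")
  df
}

#' Write QTL intervals
#' @param intervals a `qtl_intervals`.
#' @param path file path.
#' @inheritParams write_map
#' @export
write_intervals <- function(intervals, path, command = "polyqtl", seed = NA) {
  .write_table(intervals$table, path, command, seed)
}

#' Write a power report
#' @param results data.frame of power metrics (e.g.
#'   `run_experiment()$results`).
#' @param path file path.
#' @inheritParams write_map
#' @export
write_report <- function(results, path, command = "polyqtl", seed = NA) {
  .write_table(results, path, command, seed)
}

#' Read an experiment configuration
#'
#' JSON (default) or YAML (by extension, requires the yaml package). Keys
#' override [experiment_config()] defaults.
#'
#' @param path file path.
#' @return A `pq_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  scale <- if (is.null(vals$scale)) 1 else vals$scale
  vals$scale <- NULL
  if (!is.null(vals$qtl_major)) vals$qtl_major <- as.data.frame(vals$qtl_major)
  do.call(experiment_config, c(list(scale = scale), vals))
}
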