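# Shared small fixtures, generated in code under fixed seeds.

# small two-chromosome map, deterministic positions
tiny_map <- function(n = 60, len = c(30, 30)) {
  k <- n / length(len)
  genetic_map(marker = paste0("c", rep(seq_along(len), each = k), "_m",
                              rep(seq_len(k), length(len))),
              chromosome = rep(seq_along(len), each = k),
              position_cM = unlist(lapply(len, function(L)
                seq(0, L, length.out = k))))
}

# hand-built phased population: `states` is a (n_ind*ploidy) x m 0/1 matrix;
# every homologue gets its own founder label so IBD alleles are the
# homologues themselves unless labels are supplied
toy_pop <- function(states, ploidy = 4, map = NULL, labels = NULL) {
  H <- nrow(states); m <- ncol(states)
  if (is.null(map))
    map <- genetic_map(paste0("m", seq_len(m)), rep(1, m), seq_len(m) - 1)
  if (is.null(labels)) labels <- matrix(rep(seq_len(H), m), nrow = H)
  lookup <- matrix(NA_integer_, max(labels), m)
  lookup[cbind(as.vector(labels), rep(seq_len(m), each = H))] <-
    as.vector(states)
  structure(list(labels = labels, states_lookup = lookup,
                 individual = paste0("I", seq_len(H / ploidy)),
                 family = rep(0L, H / ploidy), n_ind = H / ploidy,
                 ploidy = ploidy, map = map,
                 label_ag = rep(1L, max(labels))),
            class = c("nam_pop", "phased_pop"))
}

# one shared simulated NAM population (3 ancestral groups, moderate drift),
# reused across statistical tests; ~145 individuals, 200 markers
.fixture_env <- new.env()
shared_nam <- function() {
  if (is.null(.fixture_env$nam)) {
    set.seed(20240301)
    map <- synthetic_map(200, c(40, 40))
    ags <- simulate_ag_pool(3, map, n_founders = 10, generations = 15,
                            size = 40)
    nam <- build_nam(ags, diversity_k = 3, n_peripheral = 9,
                     offspring_per_cross = 15)
    qt <- qtl_spec(data.frame(chromosome = c("1", "2"),
                              position_cM = c(20, 25)),
                   n_polygenic = 8, map = map)
    eff <- assign_effects(nam, qt)
    y <- phenotype(nam, eff)
    .fixture_env$nam <- list(map = map, ags = ags, nam = nam, qt = qt,
                             eff = eff, y = y)
  }
  .fixture_env$nam
}

# bare qtl_scan data.frame for interval/power tests
fake_scan <- function(position, neglog10p, chromosome = "1",
                      model = "snp") {
  df <- data.frame(locus = paste0("m", seq_along(position)),
                   chromosome = rep(chromosome, length.out = length(position)),
                   position_cM = position, F = NA_real_, df1 = 1L,
                   neglog10p = neglog10p, model = model,
                   untestable = FALSE, stringsAsFactors = FALSE)
  df <- df[order(match(df$chromosome, unique(df$chromosome)),
                 df$position_cM), ]
  class(df) <- c("qtl_scan", "data.frame")
  df
}
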