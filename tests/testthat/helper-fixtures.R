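# Shared fixtures: pedigrees and herd configurations built in code.

# random valid pedigree: founders plus descendants with random known parents
random_pedigree <- function(n) {
  ids <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 3L) next
    if (stats::runif(1) < 0.7) sire[i] <- ids[sample(i - 1L, 1L)]
    if (stats::runif(1) < 0.7) {
      d <- sample(i - 1L, 1L)
      if (is.na(sire[i]) || ids[d] != sire[i]) dam[i] <- ids[d]
    }
  }
  data.frame(animal = ids, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# founder pair, two full sibs, and an inbred full-sib-mating offspring
fullsib_pedigree <- function() {
  data.frame(animal = c("A", "B", "C", "D", "E"),
             sire = c(NA, NA, "A", "A", "C"),
             dam = c(NA, NA, "B", "B", "D"),
             stringsAsFactors = FALSE)
}

write_ped_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# small synthetic-herd configuration for fast end-to-end tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_founder_sires = 15L, n_founder_dams = 80L,
             daughters_per_dam = 3L, seed = seed, ...)
}

# recovery-scale truth: h2 = 0.30 (continuous) / 0.25 (liability), rg = 0.6
recovery_truth <- function() {
  spc <- 6.5
  sa <- c(rep(0.3 * spc, 3), 1 / 3)
  se <- c(rep(0.7 * spc, 3), 1)
  rg <- matrix(0.6, 4, 4); diag(rg) <- 1
  G <- rg * sqrt(outer(sa, sa))
  rr <- matrix(0.1, 4, 4); diag(rr) <- 1
  R <- rr * sqrt(outer(se, se)); diag(R) <- se
  list(G = G, R = R, h2 = c(0.3, 0.3, 0.3, 0.25), rg = 0.6)
}
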