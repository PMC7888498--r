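test_that("pedigree simulation produces the configured family structure", {
  cfg <- sim_config(n_founder_sires = 1L, n_founder_dams = 1L,
                    daughters_per_dam = 2L, n_generations = 1L, seed = 1)
  set.seed(1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4L)
  expect_equal(sum(ped$recorded), 2L)
  kids <- ped[ped$recorded, ]
  expect_equal(unique(kids$sire), "S0_0001")
  expect_equal(unique(kids$dam), "D0_0001")

  cfg0 <- sim_config(n_founder_sires = 5L, n_founder_dams = 5L,
                     n_generations = 0L)
  expect_equal(nrow(simulate_pedigree(cfg0)), 10L)
})

test_that("pedigree summary agrees with the simulator's bookkeeping", {
  set.seed(2)
  cfg <- small_sim_config(seed = 2)
  ped <- simulate_pedigree(cfg)
  rp <- ped_renumber(ped[c("animal", "sire", "dam")])
  s <- ped_summary(rp, ped$animal[ped$recorded])
  expect_equal(s$n_base_animals, cfg$n_founder_sires + cfg$n_founder_dams)
  expect_equal(s$n_with_records, sum(ped$recorded))
  expect_equal(s$n_sires_with_progeny,
               length(unique(ped$sire[ped$recorded])))
  expect_equal(s$n_dams_with_progeny,
               length(unique(ped$dam[ped$recorded])))
  expect_equal(s$n_both_unknown, sum(is.na(ped$sire) & is.na(ped$dam)))
})

test_that("gene dropping reproduces the additive covariance structure", {
  set.seed(3)
  G <- matrix(c(1, 0.5, 0.5, 2), 2)
  founders <- data.frame(animal = sprintf("F%05d", 1:8000),
                         sire = NA_character_, dam = NA_character_)
  a <- drop_breeding_values(ped_renumber(founders), G)
  expect_equal(unname(cov(a)), G, tolerance = 0.08)

  # full sibs correlate 0.5 per trait over replicate families
  nfam <- 6000
  ped <- data.frame(
    animal = c(sprintf("S%05d", 1:nfam), sprintf("D%05d", 1:nfam),
               sprintf("X%05d", 1:nfam), sprintf("Y%05d", 1:nfam)),
    sire = c(rep(NA, 2 * nfam), sprintf("S%05d", 1:nfam), sprintf("S%05d", 1:nfam)),
    dam = c(rep(NA, 2 * nfam), sprintf("D%05d", 1:nfam), sprintf("D%05d", 1:nfam)))
  av <- drop_breeding_values(ped_renumber(ped), G)
  sib1 <- av[sprintf("X%05d", 1:nfam), 1]
  sib2 <- av[sprintf("Y%05d", 1:nfam), 1]
  expect_equal(cor(sib1, sib2), 0.5, tolerance = 0.05)
  # zero additive variance propagates exactly
  a0 <- drop_breeding_values(ped_renumber(founders[1:10, ]),
                             matrix(0, 2, 2))
  expect_true(all(a0 == 0))
})

test_that("simulated records respect the AFF truncation and threshold rule", {
  set.seed(4)
  herd <- simulate_herd(small_sim_config(seed = 4))
  expect_true(all(herd$sows$aff >= 280 & herd$sows$aff <= 460))
  expect_equal(herd$stay_true, as.integer(herd$liability > 0))
  # calendar consistency: farrowing dates strictly increase with parity
  expect_true(all(diff(t(unclass(herd$farrow_dates))) > 0))
})

test_that("a zero-variance herd hits the probit of the stayability intercept", {
  set.seed(5)
  cfg <- sim_config(n_founder_sires = 10L, n_founder_dams = 500L,
                    daughters_per_dam = 40L,
                    true_G = matrix(0, 4, 4), cg_effect_sd = rep(0, 4),
                    aff_slope = rep(0, 4),
                    intercepts = c(9.4, 10, 10.5, 0.7),
                    censor_frac = 0, seed = 5)
  herd <- simulate_herd(cfg)
  expect_equal(length(herd$stay_true), 20000L)
  expect_equal(mean(herd$stay_true), pnorm(0.7), tolerance = 0.01)
})

test_that("culling deletes litters after the removal parity at the configured rates", {
  set.seed(6)
  cfg <- small_sim_config(seed = 6, culling = "random",
                          removal_probs = c(1 / 3, 1 / 3, 1 / 3),
                          censor_frac = 0)
  herd <- simulate_herd(cfg)
  tab <- herd_analysis_table(herd)
  culled <- which(herd$stay_true == 0L)
  # removal at parity p deletes nba_{p+1..3}
  expect_true(all(is.na(tab$nba2[herd$removal_parity == 1L])))
  expect_true(all(!is.na(tab$nba2[which(herd$removal_parity >= 2L)])))
  expect_true(all(is.na(tab$nba3[which(herd$removal_parity <= 2L)])))
  tt <- table(herd$removal_parity)
  expect_gt(chisq.test(tt, p = rep(1 / 3, 3))$p.value, 0.001)
  # no culling, no censoring: nothing deleted
  cfg2 <- small_sim_config(seed = 7, censor_frac = 0)
  h2 <- simulate_herd(cfg2)
  t2 <- herd_analysis_table(h2)
  expect_false(anyNA(t2$nba3[h2$stay_true == 1L]))
})

test_that("liability-linked culling removes the lowest liabilities earliest", {
  set.seed(8)
  herd <- simulate_herd(small_sim_config(seed = 8, censor_frac = 0))
  l1 <- herd$liability[which(herd$removal_parity == 1L)]
  l3 <- herd$liability[which(herd$removal_parity == 3L)]
  expect_lt(max(l1), min(l3) + 1e-12)
})

test_that("realized heritability matches the configured truth at scale", {
  set.seed(9)
  tr <- recovery_truth()
  cfg <- sim_config(n_founder_sires = 100L, n_founder_dams = 1000L,
                    daughters_per_dam = 10L, true_G = tr$G, true_R = tr$R,
                    cg_effect_sd = rep(0, 4), aff_slope = rep(0, 4),
                    censor_frac = 0, seed = 9)
  herd <- simulate_herd(cfg)
  y <- herd$nba[, 1]
  a <- herd$bv[herd$sows$sow, 1]
  # regression of breeding value on phenotype estimates h2
  expect_lt(abs(unname(coef(lm(a ~ y))[2]) - 0.3), 0.03)
})

test_that("the written herd round-trips through the editing pipeline", {
  set.seed(10)
  herd <- simulate_herd(small_sim_config(seed = 10))
  dir <- tempfile()
  write_herd(herd, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pedigree.csv", "records.csv", "truth_G.csv", "truth_R.csv",
      "breeding_values.csv")))))
  res <- edit_records(read_sow_records(file.path(dir, "records.csv")))
  expect_equal(res$log$n_dropped, 0L)
  got <- res$data
  want <- herd_analysis_table(herd)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$cg, want$cg)
  expect_equal(got$aff, want$aff)
  expect_equal(got$nba1, want$nba1)
  expect_equal(got$nba2, want$nba2)
  expect_equal(got$nba3, want$nba3)
  expect_equal(got$stay14, want$stay14)
  # pedigree file parses and covers every recorded sow
  rp <- ped_renumber(read_pedigree(file.path(dir, "pedigree.csv")))
  expect_true(all(want$sow %in% rp$id))
})

test_that("simulation configs are validated before anything is written", {
  badG <- matrix(c(1, 2, 0, 0,  2, 1, 0, 0,  0, 0, 1, 0,  0, 0, 0, 1), 4)
  expect_error(sim_config(true_G = badG), "positive definite")
  badR <- diag(c(1, 1, 1, 2))
  expect_error(sim_config(true_R = badR), "must be 1")
  expect_error(sim_config(removal_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(censor_frac = 1.2), "censor_frac")
})
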