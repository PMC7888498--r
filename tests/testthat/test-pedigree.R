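test_that("pedigree files parse, with unknown tokens and validation errors", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("A,0,0", "B,0,0", "C,A,B"), p)
  ped <- read_pedigree(p)
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$sire[3], "A")
  expect_equal(ped$dam[3], "B")
  expect_true(all(is.na(ped$sire[1:2])))

  writeLines(c("animal,sire,dam", "A,0,0", "C,A,0"), p)
  expect_equal(nrow(read_pedigree(p)), 2L)

  writeLines(c("A,0,0", "C,C,B"), p)
  expect_error(read_pedigree(p), "own parent.*C")

  writeLines(c("A,0,0", "A,0,0"), p)
  expect_error(read_pedigree(p), "duplicate.*A")

  writeLines(c("x,y", "A,0"), p)
  expect_error(read_pedigree(p, header = TRUE), "missing column")
})

test_that("renumbering is topological and promotes bare parents to founders", {
  ped <- data.frame(animal = c("C", "A", "B"),
                    sire = c("A", NA, NA), dam = c("B", NA, NA))
  rp <- ped_renumber(ped)
  expect_s3_class(rp, "renum_ped")
  expect_true(all(rp$sire < seq_len(rp$n)))
  expect_true(all(rp$dam < seq_len(rp$n)))
  expect_equal(sort(rp$id[1:2]), c("A", "B"))
  expect_equal(rp$id[3], "C")

  cyc <- data.frame(animal = c("A", "B"), sire = c("B", "A"),
                    dam = c(NA, NA))
  expect_error(ped_renumber(cyc), "cycle")

  orphan <- data.frame(animal = "C", sire = "S", dam = NA)
  expect_warning(rp2 <- ped_renumber(orphan), "promoted to founders")
  expect_equal(rp2$n, 2L)
  expect_true("S" %in% rp2$id)
})

test_that("inbreeding matches hand-computed values on classic matings", {
  rp <- ped_renumber(fullsib_pedigree())
  Fv <- ped_inbreeding(rp)
  names(Fv) <- rp$id
  expect_equal(unname(Fv[c("A", "B", "C", "D")]), rep(0, 4))
  # offspring of full sibs sharing founder parents
  expect_equal(unname(Fv["E"]), 0.25)

  # parent-offspring mating with founder grandparents
  po <- data.frame(animal = c("A", "B", "C", "X"),
                   sire = c(NA, NA, "A", "A"),
                   dam = c(NA, NA, "B", "C"))
  Fpo <- ped_inbreeding(ped_renumber(po))
  expect_equal(Fpo[4], 0.25)
})

test_that("tabular A has the expected entries on small pedigrees", {
  two <- ped_renumber(data.frame(animal = c("A", "B"), sire = NA, dam = NA))
  expect_equal(unname(ped_a_matrix(two)), diag(2))

  trio <- ped_renumber(data.frame(animal = c("A", "B", "C"),
                                  sire = c(NA, NA, "A"),
                                  dam = c(NA, NA, "B")))
  A <- ped_a_matrix(trio)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["B", "C"], 0.5)
  expect_equal(A["C", "C"], 1)

  fs <- ped_renumber(fullsib_pedigree())
  Afs <- ped_a_matrix(fs)
  expect_equal(Afs["C", "D"], 0.5)
  # diag(A) = 1 + F
  expect_equal(unname(diag(Afs)), unname(1 + ped_inbreeding(fs)))

  expect_error(ped_a_matrix(two, max_n = 1L), "refusing")
})

test_that("sparse A-inverse inverts the tabular A on random pedigrees", {
  set.seed(42)
  worst <- 0
  for (k in 1:30) {
    rp <- ped_renumber(random_pedigree(sample(20:100, 1)))
    A <- ped_a_matrix(rp)
    Ai <- as.matrix(ped_a_inverse(rp))
    worst <- max(worst, max(abs(Ai %*% A - diag(rp$n))))
    if (k <= 5) expect_no_error(chol(A))  # A positive definite
  }
  expect_lt(worst, 1e-8)
})

test_that("A-inverse follows the parent-offspring rules exactly", {
  founders <- ped_renumber(data.frame(animal = c("A", "B", "C"),
                                      sire = NA, dam = NA))
  expect_equal(as.matrix(ped_a_inverse(founders)), diag(3),
               ignore_attr = TRUE)

  trio <- ped_renumber(data.frame(animal = c("A", "B", "C"),
                                  sire = c(NA, NA, "A"),
                                  dam = c(NA, NA, "B")))
  Ai <- as.matrix(ped_a_inverse(trio))
  # offspring of non-inbred parents: d = 0.5, diagonal entry 2
  expect_equal(Ai[3, 3], 2)
  expect_equal(Ai[1, 3], -1)
  expect_equal(Ai[1, 2], 0.5)
})

test_that("renumbering is invariant to input row order", {
  set.seed(7)
  ped <- random_pedigree(40)
  rp1 <- ped_renumber(ped)
  rp2 <- ped_renumber(ped[sample(nrow(ped)), ])
  A1 <- ped_a_matrix(rp1)
  A2 <- ped_a_matrix(rp2)
  expect_equal(A1[rp1$id, rp1$id], A2[rp1$id, rp1$id])
})

test_that("pedigree summary counts base animals, records and parents", {
  ped <- data.frame(animal = c(paste0("F", 1:5), "X", "Y", "Z"),
                    sire = c(rep(NA, 5), "F1", "F1", "F2"),
                    dam = c(rep(NA, 5), "F3", "F4", NA))
  rp <- ped_renumber(ped)
  s <- ped_summary(rp, c("X", "Y", "Z"))
  expect_equal(s$n_base_animals, 5L)
  expect_equal(s$n_with_records, 3L)
  expect_equal(s$n_unknown_dam, 1L)   # Z has sire only
  expect_equal(s$n_unknown_sire, 0L)
  expect_equal(s$n_both_unknown, 5L)
  expect_equal(s$n_sires_with_progeny, 2L)  # F1, F2
  expect_equal(s$n_dams_with_progeny, 2L)   # F3, F4
  # base + animals with at least one known parent = total
  expect_equal(s$n_base_animals + 3L, s$n_animals)
  expect_error(ped_summary(rp, "nope"), "absent from pedigree")
})

test_that("A-inverse exports to MatrixMarket coordinate format", {
  rp <- ped_renumber(fullsib_pedigree())
  f <- tempfile(fileext = ".mtx")
  write_a_inverse(ped_a_inverse(rp), f)
  expect_true(file.exists(f))
  back <- Matrix::readMM(f)
  expect_equal(as.matrix(back), as.matrix(ped_a_inverse(rp)),
               ignore_attr = TRUE, tolerance = 1e-12)
})
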