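#' Read a pedigree file
#'
#' Reads a delimited pedigree with one row per animal and columns
#' `animal`, `sire`, `dam`. Unknown parents are written with a
#' configurable token (default `"0"`; empty fields are always treated
#' as unknown).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default `","`).
#' @param unknown Token denoting an unknown parent (default `"0"`).
#' @param header Logical; does the file carry a header row? If `NA`
#'   (default) the first line is inspected for the literal column names.
#' @return A data frame with character columns `animal`, `sire`, `dam`;
#'   unknown parents are `NA`.
#' @seealso [ped_renumber()]
#' @export
read_pedigree <- function(path, sep = ",", unknown = "0", header = NA) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.na(header)) {
    first <- tolower(strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]])
    header <- all(c("animal", "sire", "dam") %in% trimws(first))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", strip.white = TRUE,
                          stringsAsFactors = FALSE, fill = FALSE)
  if (!header) {
    if (ncol(df) < 3L) stop("pedigree file must have columns animal, sire, dam")
    names(df)[1:3] <- c("animal", "sire", "dam")
  }
  names(df) <- tolower(names(df))
  miss <- setdiff(c("animal", "sire", "dam"), names(df))
  if (length(miss)) stop("pedigree file missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[c("animal", "sire", "dam")]
  df$sire[df$sire %in% c(unknown, "")] <- NA_character_
  df$dam[df$dam %in% c(unknown, "")] <- NA_character_
  validate_pedigree(df)
}

#' @keywords internal
validate_pedigree <- function(df) {
  if (any(is.na(df$animal) | df$animal == ""))
    stop("pedigree contains empty animal identifiers")
  dup <- unique(df$animal[duplicated(df$animal)])
  if (length(dup))
    stop("duplicate animal id(s) in pedigree: ", paste(dup, collapse = ", "))
  own <- df$animal == df$sire | df$animal == df$dam
  own[is.na(own)] <- FALSE
  if (any(own))
    stop("animal listed as its own parent: ",
         paste(df$animal[own], collapse = ", "))
  df
}

#' Renumber a pedigree so parents precede offspring
#'
#' Assigns integer codes 1..n in a topological order (every parent's
#' code is smaller than its offspring's). Identifiers appearing only as
#' parents are promoted to founders with a warning, matching the usual
#' bookkeeping in which sires and dams need not have own records.
#'
#' @param ped A data frame as returned by [read_pedigree()], or any data
#'   frame with character columns `animal`, `sire`, `dam` (`NA` =
#'   unknown parent).
#' @return An object of class `"renum_ped"`: a list with
#'   \describe{
#'     \item[id]{original identifier for each code 1..n,}
#'     \item[sire, dam]{integer parent codes (0 = unknown),}
#'     \item[n]{number of animals.}
#'   }
#' @export
ped_renumber <- function(ped) {
  ped <- validate_pedigree(ped[c("animal", "sire", "dam")])
  extra <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(extra)) {
    warning(length(extra),
            " parent id(s) without own pedigree row promoted to founders: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ...")
    ped <- rbind(data.frame(animal = extra, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  # longest-ancestor-path "generation" number; cycles never stabilise
  gen <- ifelse(is.na(si) & is.na(di), 0L, NA_integer_)
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    gs <- ifelse(is.na(si[todo]), 0L, gen[si[todo]])
    gd <- ifelse(is.na(di[todo]), 0L, gen[di[todo]])
    ready <- !is.na(gs) & !is.na(gd)
    if (!any(ready))
      stop("pedigree cycle involving: ",
           paste(ped$animal[todo], collapse = ", "))
    gen[todo[ready]] <- pmax(gs[ready], gd[ready]) + 1L
  }
  ord <- order(gen, seq_len(n))
  code <- integer(n)
  code[ord] <- seq_len(n)
  out <- list(id = ped$animal[ord],
              sire = ifelse(is.na(si), 0L, code[si])[ord],
              dam = ifelse(is.na(di), 0L, code[di])[ord],
              n = n)
  class(out) <- "renum_ped"
  out
}

#' @export
print.renum_ped <- function(x, ...) {
  cat("Renumbered pedigree:", x$n, "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders\n")
  invisible(x)
}

#' Look up pedigree codes for original identifiers
#' @param ped A `renum_ped`.
#' @param ids Character vector of original identifiers.
#' @keywords internal
ped_code <- function(ped, ids) {
  m <- match(ids, ped$id)
  if (anyNA(m))
    stop("identifier(s) absent from pedigree: ",
         paste(unique(ids[is.na(m)]), collapse = ", "))
  m
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient of every animal with the
#' Meuwissen-Luo algorithm (equivalent to F_i = a(sire_i, dam_i)/2
#' from the tabular relationship matrix, without forming it).
#'
#' @param ped A `renum_ped` from [ped_renumber()].
#' @return Numeric vector of inbreeding coefficients, one per code.
#' @export
ped_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "renum_ped"))
  inbreeding_ml(ped$sire, ped$dam)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense reference construction of A: `a(i,i) = 1 + F_i` and
#' `a(i,j) = (a(j, sire_i) + a(j, dam_i)) / 2` with unknown parents
#' contributing 0. Intended as an oracle for small pedigrees and guarded
#' against accidental use at scale.
#'
#' @param ped A `renum_ped`.
#' @param max_n Refuse pedigrees larger than this (default 5000).
#' @return Dense symmetric matrix of order `ped$n`, dimnames = original ids.
#' @export
ped_a_matrix <- function(ped, max_n = 5000L) {
  stopifnot(inherits(ped, "renum_ped"))
  n <- ped$n
  if (n > max_n)
    stop("tabular A is a dense oracle; refusing n = ", n, " > ", max_n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- A[i, j] <- aij
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by the standard
#' parent-offspring rules. With `inbreeding = TRUE` (default) the
#' Mendelian-sampling variance of animal i is
#' `d_i = 1 - 0.25 (1 + F_s) - 0.25 (1 + F_d)`, each parental term
#' dropped when the parent is unknown; each animal then contributes
#' `1/d_i` at (i,i), `-0.5/d_i` at (i, parent) and `0.25/d_i` at each
#' known (parent, parent) pair.
#'
#' @param ped A `renum_ped`.
#' @param inbreeding Logical; account for parental inbreeding in the
#'   Mendelian-sampling variances (default `TRUE`).
#' @param F Optional precomputed inbreeding vector (ignored when
#'   `inbreeding = FALSE`).
#' @return A symmetric sparse matrix (class `dsCMatrix` from Matrix).
#' @export
ped_a_inverse <- function(ped, inbreeding = TRUE, F = NULL) {
  stopifnot(inherits(ped, "renum_ped"))
  n <- ped$n
  Fv <- if (!inbreeding) numeric(n) else if (is.null(F)) ped_inbreeding(ped) else F
  s <- ped$sire; d <- ped$dam
  ks <- s > 0L; kd <- d > 0L
  dvec <- 1 - ifelse(ks, 0.25 * (1 + Fv[pmax(s, 1L)]), 0) -
              ifelse(kd, 0.25 * (1 + Fv[pmax(d, 1L)]), 0)
  if (any(dvec <= 0))
    stop("non-positive Mendelian sampling variance; inbreeding vector corrupt?")
  al <- 1 / dvec
  i <- seq_len(n)
  ii <- c(i, i[ks], i[kd], s[ks], d[kd], s[ks & kd], d[ks & kd],
          s[ks], d[kd])
  jj <- c(i, s[ks], d[kd], i[ks], i[kd], d[ks & kd], s[ks & kd],
          s[ks], d[kd])
  xx <- c(al, -0.5 * al[ks], -0.5 * al[kd], -0.5 * al[ks], -0.5 * al[kd],
          0.25 * al[ks & kd], 0.25 * al[ks & kd],
          0.25 * al[ks], 0.25 * al[kd])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               repr = "C")
  Matrix::forceSymmetric(Ainv)
}

#' Export A-inverse in MatrixMarket coordinate format
#' @param ainv Sparse matrix from [ped_a_inverse()].
#' @param path Output file path.
#' @export
write_a_inverse <- function(ainv, path) {
  Matrix::writeMM(methods::as(ainv, "generalMatrix"), path)
  invisible(path)
}

#' Pedigree structure summary
#'
#' Counts the quantities conventionally reported for an animal-model
#' pedigree: base animals (both parents unknown), animals with own
#' records, unknown-parent patterns, and sires/dams with recorded
#' progeny.
#'
#' @param ped A `renum_ped`.
#' @param record_ids Character vector of identifiers of animals with
#'   phenotype records; must all be present in the pedigree.
#' @return A one-row data frame of counts.
#' @export
ped_summary <- function(ped, record_ids) {
  stopifnot(inherits(ped, "renum_ped"))
  rc <- ped_code(ped, unique(record_ids))
  both_unknown <- ped$sire == 0L & ped$dam == 0L
  data.frame(
    n_animals = ped$n,
    n_base_animals = sum(both_unknown),
    n_with_records = length(rc),
    n_unknown_sire = sum(ped$sire == 0L & ped$dam != 0L),
    n_unknown_dam = sum(ped$dam == 0L & ped$sire != 0L),
    n_both_unknown = sum(both_unknown),
    n_sires_with_progeny = length(unique(ped$sire[rc][ped$sire[rc] > 0L])),
    n_dams_with_progeny = length(unique(ped$dam[rc][ped$dam[rc] > 0L]))
  )
}
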