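#' Build a nuclear-family pedigree
#'
#' Generates a pedigree of unrelated nuclear families (two founder parents
#' plus a sampled number of full sibs) covering exactly `n_individuals`.
#' When fewer than three individuals remain to be placed, they are emitted
#' as singleton founders so the total is met exactly. Parents always precede
#' their children in row order, which downstream kinship computation relies
#' on.
#'
#' @param n_individuals Total number of individuals (positive integer).
#' @param sibship_sizes Integer vector of sibship sizes to sample from
#'   (default `2:4`), one draw per family.
#' @param seed Optional integer seed; if supplied the pedigree is a pure
#'   function of the arguments.
#' @return A data frame of class `methgene_pedigree` with columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id` (`NA` for
#'   founders) and `sex` (1 = male, 2 = female).
#' @examples
#' ped <- build_pedigree(10, seed = 1)
#' table(is.na(ped$father_id))
#' @export
build_pedigree <- function(n_individuals, sibship_sizes = 2:4, seed = NULL) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      is.na(n_individuals) || n_individuals < 1 ||
      n_individuals != round(n_individuals)) {
    stop("`n_individuals` must be a single positive integer.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  sibship_sizes <- as.integer(sibship_sizes)
  if (any(sibship_sizes < 1L)) stop("`sibship_sizes` must be positive.")

  fam_id <- character(n); ind_id <- character(n)
  fat_id <- rep(NA_character_, n); mot_id <- rep(NA_character_, n)
  sex <- integer(n)
  i <- 0L; f <- 0L
  while (i < n) {
    f <- f + 1L
    remaining <- n - i
    fid <- sprintf("FAM%04d", f)
    if (remaining <= 2L) {
      # not enough left for two parents + at least one child: singleton founder
      i <- i + 1L
      fam_id[i] <- fid; ind_id[i] <- sprintf("I%05d", i)
      sex[i] <- sample(1:2, 1L)
      next
    }
    k <- if (length(sibship_sizes) == 1L) sibship_sizes else sample(sibship_sizes, 1L)
    k <- min(k, remaining - 2L)
    fa <- sprintf("I%05d", i + 1L); mo <- sprintf("I%05d", i + 2L)
    fam_id[i + 1L] <- fid; ind_id[i + 1L] <- fa; sex[i + 1L] <- 1L
    fam_id[i + 2L] <- fid; ind_id[i + 2L] <- mo; sex[i + 2L] <- 2L
    for (c in seq_len(k)) {
      j <- i + 2L + c
      fam_id[j] <- fid; ind_id[j] <- sprintf("I%05d", j)
      fat_id[j] <- fa; mot_id[j] <- mo
      sex[j] <- sample(1:2, 1L)
    }
    i <- i + 2L + k
  }
  ped <- data.frame(family_id = fam_id, individual_id = ind_id,
                    father_id = fat_id, mother_id = mot_id, sex = sex,
                    stringsAsFactors = FALSE)
  class(ped) <- c("methgene_pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  req <- c("family_id", "individual_id", "father_id", "mother_id")
  if (!all(req %in% names(ped))) {
    stop("pedigree must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ped$individual_id)) stop("duplicated individual ids in pedigree")
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$individual_id
  fi <- unname(idx[ped$father_id]); mi <- unname(idx[ped$mother_id])
  known <- !is.na(ped$father_id)
  if (any(known & is.na(fi))) stop("father id not present in pedigree")
  if (any(!is.na(ped$mother_id) & is.na(mi))) stop("mother id not present in pedigree")
  # parents strictly before children rules out cycles and self-ancestry
  if (any(fi >= idx, na.rm = TRUE) || any(mi >= idx, na.rm = TRUE)) {
    stop("pedigree ordering invalid: every parent must precede its children")
  }
  list(father = fi, mother = mi)
}

#' Expected kinship matrix from a pedigree
#'
#' Computes the matrix of expected kinship coefficients by the recursive
#' tabular method: for individual `i` with parents `(f, m)` and any earlier
#' individual `j`, `phi(i, j) = (phi(f, j) + phi(m, j)) / 2` and
#' `phi(i, i) = (1 + phi(f, m)) / 2`. Founders are taken as mutually
#' unrelated and non-inbred, so their diagonal is 0.5. The polygenic
#' covariance used in the stage-1 mixed model is `2 * Phi * sigma2_g`.
#'
#' @param ped A pedigree as returned by [build_pedigree()] (parents must
#'   precede children).
#' @return An `n x n` symmetric matrix with individual ids as dimnames.
#' @examples
#' ped <- build_pedigree(5, sibship_sizes = 3, seed = 1)
#' kinship_from_pedigree(ped)["I00003", "I00004"] # full sibs: 0.25
#' @export
kinship_from_pedigree <- function(ped) {
  par <- validate_pedigree(ped)
  n <- nrow(ped)
  phi <- matrix(0, n, n)
  fi <- par$father; mi <- par$mother
  for (i in seq_len(n)) {
    if (is.na(fi[i]) && is.na(mi[i])) {
      phi[i, i] <- 0.5
      next
    }
    prev <- seq_len(i - 1L)
    pf_ <- if (is.na(fi[i])) rep(0, i - 1L) else phi[fi[i], prev]
    pm_ <- if (is.na(mi[i])) rep(0, i - 1L) else phi[mi[i], prev]
    v <- (pf_ + pm_) / 2
    phi[i, prev] <- v
    phi[prev, i] <- v
    fm <- if (is.na(fi[i]) || is.na(mi[i])) 0 else phi[fi[i], mi[i]]
    phi[i, i] <- (1 + fm) / 2
  }
  dimnames(phi) <- list(ped$individual_id, ped$individual_id)
  phi
}

#' Write / read a FAM-style pedigree file
#'
#' Plain-text, whitespace-delimited, one row per individual:
#' `FID IID PAT MAT SEX PHENO`, with `0` for unknown parents and `-9` for
#' the (unused) phenotype column.
#'
#' @param ped Pedigree data frame.
#' @param path Output file path.
#' @return `write_fam()` returns `path` invisibly; `read_fam()` returns a
#'   `methgene_pedigree` data frame.
#' @export
write_fam <- function(ped, path) {
  out <- data.frame(FID = ped$family_id, IID = ped$individual_id,
                    PAT = ifelse(is.na(ped$father_id), "0", ped$father_id),
                    MAT = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    SEX = if ("sex" %in% names(ped)) ped$sex else 0L,
                    PHENO = -9)
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("FID", "IID", "PAT", "MAT", "SEX", "PHENO"))
  ped <- data.frame(family_id = as.character(x$FID),
                    individual_id = as.character(x$IID),
                    father_id = ifelse(x$PAT == "0", NA_character_, as.character(x$PAT)),
                    mother_id = ifelse(x$MAT == "0", NA_character_, as.character(x$MAT)),
                    sex = as.integer(x$SEX), stringsAsFactors = FALSE)
  class(ped) <- c("methgene_pedigree", "data.frame")
  ped
}
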