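#' Pair each SNP with its nearest CpG site
#'
#' Every SNP is paired with the CpG on the same chromosome minimizing the
#' point-to-point basepair distance; distance ties are broken toward the
#' lower-coordinate CpG so the pairing is deterministic. An override table
#' (e.g. mapping a major-effect SNP to a designated "causal" CpG that need
#' not be the nearest) takes precedence; overrides farther than
#' `max_override_bp` raise a warning. A CpG may serve several SNPs, but each
#' SNP maps to exactly one CpG.
#'
#' @param geno A `snp_matrix` (typically already QC-filtered).
#' @param meth A `cpg_matrix`.
#' @param overrides Optional data frame with columns `snp_id`, `cpg_id`.
#' @param max_override_bp Warn when an override pair is farther apart than
#'   this (default 12500 bp).
#' @return An object of class `pair_map`: list with `pairs` (data frame:
#'   `snp_id`, `cpg_id`, `chrom`, `snp_pos`, `cpg_pos`, `distance`,
#'   `override`), and empty `genes` / `gene_info` slots to be filled by
#'   [assemble_gene_sets()].
#' @export
pair_snps_to_cpgs <- function(geno, meth, overrides = NULL,
                              max_override_bp = 12500) {
  si <- geno$info; ci <- meth$info
  out <- data.frame(snp_id = si$snp_id, cpg_id = NA_character_,
                    chrom = si$chrom, snp_pos = si$pos,
                    cpg_pos = NA_integer_, stringsAsFactors = FALSE)
  for (ch in unique(si$chrom)) {
    s_idx <- which(si$chrom == ch)
    c_idx <- which(ci$chrom == ch)
    if (length(c_idx) == 0L) {
      stop("chromosome ", ch, " has SNPs but no CpG sites")
    }
    cpos <- ci$pos[c_idx]           # strictly increasing by construction
    spos <- si$pos[s_idx]
    left <- findInterval(spos, cpos)
    right <- pmin(left + 1L, length(cpos))
    left <- pmax(left, 1L)
    dl <- abs(spos - cpos[left])
    dr <- abs(spos - cpos[right])
    nearest <- ifelse(dl <= dr, left, right)  # tie toward lower coordinate
    out$cpg_id[s_idx] <- ci$cpg_id[c_idx][nearest]
    out$cpg_pos[s_idx] <- cpos[nearest]
  }
  out$override <- FALSE
  if (!is.null(overrides) && nrow(overrides) > 0) {
    stopifnot(all(c("snp_id", "cpg_id") %in% names(overrides)))
    m <- match(overrides$snp_id, out$snp_id)
    if (anyNA(m)) stop("override snp_id not among paired SNPs: ",
                       paste(overrides$snp_id[is.na(m)], collapse = ", "))
    cc <- match(overrides$cpg_id, ci$cpg_id)
    if (anyNA(cc)) stop("override cpg_id not found")
    out$cpg_id[m] <- ci$cpg_id[cc]
    out$cpg_pos[m] <- ci$pos[cc]
    out$override[m] <- TRUE
    far <- abs(out$snp_pos[m] - out$cpg_pos[m]) > max_override_bp
    if (any(far)) {
      warning(sum(far), " override pair(s) exceed ", max_override_bp,
              " bp between SNP and CpG")
    }
  }
  out$distance <- abs(out$snp_pos - out$cpg_pos)
  structure(list(pairs = out, genes = list(), gene_info = NULL),
            class = "pair_map")
}

#' Assign SNP-CpG pairs to genes and gene sets
#'
#' A pair belongs to a gene iff its SNP position lies within the gene's
#' 1-based inclusive `[start, stop]` interval on the same chromosome. A
#' designated major-effect SNP falling in no gene is appended to the
#' nearest gene within `orphan_rule_bp` of it; if none is that close, a
#' synthetic gene spanning the SNP plus/minus `orphan_rule_bp` is created
#' and receives every pair in that window. Explicit sets (unions of genes,
#' or spiked member lists such as causal-plus-noise constructions) are
#' supported through `sets`. Genes that end up empty are excluded with a
#' message.
#'
#' @param pairs A `pair_map` from [pair_snps_to_cpgs()].
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `stop` and
#'   optionally `category` (one of `major_causal`, `minor_causal`,
#'   `noncausal`, `synthetic_set`).
#' @param orphan_rule_bp Orphan attachment / synthetic-gene half-window
#'   (default 50000 bp).
#' @param major_snp_ids SNP ids subject to the orphan rule.
#' @param sets Optional named list; each element is either
#'   `list(genes = <gene ids>, category = ...)` (union set) or
#'   `list(snp_ids = <snp ids>, category = ...)` (explicit members).
#' @return The `pair_map` with `genes` (named list of pair-row indices) and
#'   `gene_info` (data frame: `gene_id`, `category`, `m`) filled in.
#' @export
assemble_gene_sets <- function(pairs, genes, orphan_rule_bp = 50000,
                               major_snp_ids = NULL, sets = NULL) {
  stopifnot(inherits(pairs, "pair_map"),
            all(c("gene_id", "chrom", "start", "stop") %in% names(genes)))
  if (any(genes$start > genes$stop)) stop("gene start must be <= stop")
  pp <- pairs$pairs
  if (!"category" %in% names(genes)) genes$category <- "noncausal"
  membership <- list(); category <- character(0)

  gene_rows <- function(g) {
    which(pp$chrom == genes$chrom[g] &
          pp$snp_pos >= genes$start[g] & pp$snp_pos <= genes$stop[g])
  }
  for (g in seq_len(nrow(genes))) {
    membership[[genes$gene_id[g]]] <- gene_rows(g)
    category[genes$gene_id[g]] <- genes$category[g]
  }
  # orphan rule for designated major-effect SNPs outside every gene
  for (snp in major_snp_ids %||% character(0)) {
    r <- match(snp, pp$snp_id)
    if (is.na(r)) next                      # e.g. removed by QC
    if (any(vapply(membership, function(ix) r %in% ix, logical(1)))) next
    same <- genes$chrom == pp$chrom[r]
    if (any(same)) {
      gap <- pmax(genes$start - pp$snp_pos[r], pp$snp_pos[r] - genes$stop, 0)
      gap[!same] <- Inf
      gmin <- which.min(gap)
    } else gmin <- NA_integer_
    if (!is.na(gmin) && gap[gmin] <= orphan_rule_bp) {
      gid <- genes$gene_id[gmin]
      membership[[gid]] <- sort(c(membership[[gid]], r))
    } else {
      gid <- paste0("SYNTH_", snp)
      win <- which(pp$chrom == pp$chrom[r] &
                   abs(pp$snp_pos - pp$snp_pos[r]) <= orphan_rule_bp)
      membership[[gid]] <- win
      category[gid] <- "major_causal"
    }
  }
  for (sid in names(sets %||% list())) {
    s <- sets[[sid]]
    if (!is.null(s$genes)) {
      miss <- setdiff(s$genes, names(membership))
      if (length(miss)) stop("set ", sid, " references unknown gene(s): ",
                             paste(miss, collapse = ", "))
      ix <- sort(unique(unlist(membership[s$genes])))
    } else {
      ix <- sort(match(intersect(s$snp_ids, pp$snp_id), pp$snp_id))
    }
    membership[[sid]] <- ix
    category[sid] <- s$category %||% "synthetic_set"
  }
  empty <- lengths(membership) == 0L
  if (any(empty)) {
    message("excluding ", sum(empty), " empty gene(s)/set(s): ",
            paste(names(membership)[empty], collapse = ", "))
    membership <- membership[!empty]
    category <- category[names(membership)]
  }
  pairs$genes <- membership
  pairs$gene_info <- data.frame(gene_id = names(membership),
                                category = unname(category[names(membership)]),
                                m = unname(lengths(membership)),
                                row.names = NULL, stringsAsFactors = FALSE)
  pairs
}
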