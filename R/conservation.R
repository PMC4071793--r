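# Per-column conservation scoring from a multiple sequence alignment,
# mapping of scores onto structure residues, and detection of the most
# conserved connected surface patch.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 background amino-acid frequencies
BG_FREQ <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
             Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
             L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
             S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)[AA20]

new_alignment <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  structure(list(mat = mat), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments (format auto-detected from the first
#' non-blank line).  Sequences are upper-cased and both `.` and `-` are read
#' as gaps.
#'
#' @param source path to an alignment file, or its text (string containing
#'   newlines).
#' @return an `aa_alignment`: list with `mat`, a character matrix (rows =
#'   sequences, named; columns = alignment columns).
#' @export
read_msa <- function(source) {
  if (length(source) == 1 && grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".msa")
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    path <- source
  }
  first <- grep("\\S", readLines(path, warn = FALSE), value = TRUE)[1]
  fmt <- if (startsWith(first, "#") || startsWith(first, "# STOCKHOLM"))
    "stockholm" else "fasta"
  if (fmt == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    w <- nchar(seqs)
    if (length(unique(w)) > 1) {
      bad <- names(seqs)[which(w != w[1])[1]]
      stop("ragged alignment: row '", bad, "' has length ", w[w != w[1]][1],
           ", expected ", w[1])
    }
    ids <- sub("\\s.*$", "", names(seqs))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & grepl("\\S", lines)]
    parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
    if (any(lengths(parts) != 3)) stop("malformed Stockholm sequence line")
    ids0 <- vapply(parts, `[`, "", 2)
    sq <- vapply(parts, `[`, "", 3)
    seqs <- vapply(split(sq, factor(ids0, levels = unique(ids0))),
                   paste, "", collapse = "")
    seqs <- toupper(seqs)
    ids <- names(seqs)
    w <- nchar(seqs)
    if (length(unique(w)) > 1)
      stop("ragged alignment: row '", ids[which(w != w[1])[1]], "'")
  }
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- ids
  new_alignment(mat)
}

#' Write an alignment as aligned FASTA
#' @param msa an `aa_alignment`
#' @param path output file
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(msa$mat, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(msa$mat)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

kl_div <- function(p, q) {
  i <- p > 0
  sum(p[i] * log2(p[i] / q[i]))
}

jsd <- function(p, q) {
  m <- (p + q) / 2
  0.5 * kl_div(p, m) + 0.5 * kl_div(q, m)
}

column_freq <- function(col, pseudo = 0.05 / 20) {
  col <- col[col %in% AA20]
  if (length(col) == 0) return(NULL)
  f <- table(factor(col, levels = AA20)) / length(col)
  f <- as.numeric(f) + pseudo
  f / sum(f)
}

#' Per-column conservation scores
#'
#' Scores each alignment column by the Jensen-Shannon divergence (base-2)
#' between the column's amino-acid frequency vector (gaps and X excluded,
#' pseudo-count 0.05/20) and a fixed BLOSUM62-derived background, normalised
#' to `[0,1]` by the divergence of a point-mass column on the column's
#' majority residue against the same background (so any invariant column
#' scores exactly 1).  With `gap_penalty` the score is further multiplied by
#' one minus the column's gap fraction.
#'
#' @param msa an `aa_alignment` with at least 2 rows
#' @param gap_penalty multiply scores by (1 - gap fraction)? Default TRUE.
#' @return data.frame with column, score (in `[0,1]`; 0 for all-gap
#'   columns) and gap_fraction.
#' @export
column_conservation <- function(msa, gap_penalty = TRUE) {
  mat <- msa$mat
  if (nrow(mat) < 2) stop("alignment must have at least 2 rows")
  L <- ncol(mat)
  score <- numeric(L)
  gapf <- colMeans(mat == "-")
  for (j in seq_len(L)) {
    p <- column_freq(mat[, j])
    if (is.null(p)) { score[j] <- 0; next }
    mode_aa <- AA20[which.max(p)]
    pm <- column_freq(rep(mode_aa, 2))
    denom <- jsd(pm, BG_FREQ)
    score[j] <- min(1, jsd(p, BG_FREQ) / denom)
  }
  if (gap_penalty) score <- score * (1 - gapf)
  data.frame(column = seq_len(L), score = score, gap_fraction = gapf)
}

#' Map alignment conservation onto structure residues
#'
#' Globally aligns the ungapped sequence of alignment row `row_id` to the
#' polymer sequence of the chosen structure chain (match 1, mismatch -1, gap
#' -2) and assigns each matched structure residue the conservation score of
#' its alignment column.  Errors if identity over structure residues is
#' below 90% (wrong row or chain).
#'
#' @param msa an `aa_alignment`
#' @param row_id row identifier of the sequence corresponding to the
#'   structure
#' @param structure a `structure3d`
#' @param chain chain id
#' @param conservation optional precomputed [column_conservation()] output.
#' @return a `conservation_profile`: list with `column_scores` (data.frame),
#'   `residue_scores` (data.frame chain, resno, icode, key, column, score)
#'   and `identity`.
#' @export
map_to_structure <- function(msa, row_id, structure, chain,
                             conservation = NULL) {
  if (!row_id %in% rownames(msa$mat)) stop("row '", row_id, "' not in alignment")
  if (is.null(conservation)) conservation <- column_conservation(msa)
  row <- msa$mat[row_id, ]
  nongap <- which(row != "-")
  rowseq <- paste(row[nongap], collapse = "")

  sq <- extract_sequence(structure, chain)
  alpha <- unique(c(AA20, "X", "U", "O", strsplit(paste0(rowseq, sq$sequence), "")[[1]]))
  submat <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(rowseq, sq$sequence,
                                       substitutionMatrix = submat,
                                       gapOpening = 0, gapExtension = 2,
                                       type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- cumsum(pat != "-")   # position in row sequence
  is <- cumsum(sub != "-")   # position in structure sequence
  matched <- pat != "-" & sub != "-"
  ident <- sum(pat[matched] == sub[matched]) / length(sq$numbers)
  if (ident < 0.9)
    stop(sprintf("alignment identity %.1f%% below 90%%: wrong row or chain?",
                 100 * ident))
  col_idx <- nongap[ip[matched]]
  res_idx <- is[matched]
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain & rt$kind == "polymer", , drop = FALSE]
  res <- rt[res_idx, , drop = FALSE]
  profile <- data.frame(chain = res$chain, resno = res$resno,
                        icode = res$icode, key = res$key, column = col_idx,
                        score = conservation$score[col_idx],
                        stringsAsFactors = FALSE)
  base::structure(list(column_scores = conservation, residue_scores = profile,
                 identity = ident), class = "conservation_profile")
}

#' Most conserved connected surface patches
#'
#' Surface residues (relative SASA >= `exposure_min`) receive a spatially
#' smoothed score (mean raw score over surface neighbours within `radius` of
#' their Calpha, self included); residues above the given score percentile
#' are clustered by Calpha-distance connectivity (<= `radius`) and the
#' resulting patches ranked by mean smoothed score times patch size.
#'
#' @param structure a `structure3d`
#' @param profile a `conservation_profile` from [map_to_structure()]
#' @param sasa output of [shrake_rupley_sasa()]
#' @param radius neighbourhood/connectivity radius in Angstrom (default 8)
#' @param exposure_min relative-SASA surface threshold (default 0.2)
#' @param percentile smoothed-score percentile for patch membership
#'   (default 80); if all smoothed scores are equal the single patch of all
#'   surface residues is returned.
#' @return list of patches, each with `keys`, `resno`, `mean_score`, `size`
#'   and `rank_score`, ordered by decreasing `rank_score`.
#' @export
conserved_patch <- function(structure, profile, sasa, radius = 8,
                            exposure_min = 0.2, percentile = 80) {
  res <- sasa$residue
  surf <- res[!is.na(res$rel_area) & res$rel_area >= exposure_min, , drop = FALSE]
  if (nrow(surf) == 0) return(list())
  sc <- profile$residue_scores$score[match(surf$key, profile$residue_scores$key)]
  sc[is.na(sc)] <- 0
  bb <- backbone_coords(structure, surf$chain[1])
  ca <- bb$CA[match(surf$key, bb$key), , drop = FALSE]
  D <- as.matrix(stats::dist(ca))
  nbr <- D <= radius
  smoothed <- as.numeric(nbr %*% sc) / rowSums(nbr)
  thr <- stats::quantile(smoothed, percentile / 100, names = FALSE)
  keep <- if (diff(range(smoothed)) < 1e-12) rep(TRUE, nrow(surf)) else smoothed >= thr
  idx <- which(keep)
  if (length(idx) == 0) return(list())
  # single-linkage clustering by Calpha connectivity
  comp <- rep(NA_integer_, length(idx))
  cid <- 0
  for (s in seq_along(idx)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    frontier <- s
    comp[s] <- cid
    while (length(frontier) > 0) {
      nxt <- which(is.na(comp) &
                     colSums(D[idx[frontier], idx, drop = FALSE] <= radius) > 0)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  patches <- lapply(split(seq_along(idx), comp), function(mem) {
    m <- idx[mem]
    list(keys = surf$key[m], resno = surf$resno[m],
         mean_score = mean(smoothed[m]), size = length(m),
         rank_score = mean(smoothed[m]) * length(m))
  })
  patches[order(vapply(patches, `[[`, 0, "rank_score"), decreasing = TRUE)]
}
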