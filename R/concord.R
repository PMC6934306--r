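#' Partition positions by replicate-membership pattern
#'
#' Exact partition of the union of per-sample bi-allelic position sets by
#' membership pattern (the counting behind an UpSet plot). Every position is
#' counted in exactly one pattern.
#'
#' @param position_sets named list; each element a character vector of
#'   `"contig:pos"` keys (see [position_keys()]).
#' @param top number of largest patterns reported by `print` (default 15,
#'   remainder bucketed).
#' @return object of class `overlap_partition`: list with `sample_ids`,
#'   `pattern_counts` (named integer vector; names are 0/1 strings over
#'   samples), `universe_size` (size of the union), `top`.
#' @export
intersect_sets <- function(position_sets, top = 15L) {
  stopifnot(length(position_sets) >= 1)
  ids <- names(position_sets) %||% paste0("set", seq_along(position_sets))
  bad <- vapply(position_sets, function(s) any(!grepl(":", s, fixed = TRUE)),
                logical(1))
  if (any(bad)) stop("positions must be 'contig:pos' keys on a common genome")
  universe <- unique(unlist(position_sets, use.names = FALSE))
  member <- vapply(position_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- sort(table(pattern), decreasing = TRUE)
  structure(list(
    sample_ids = ids,
    pattern_counts = setNames(as.integer(counts), names(counts)),
    universe_size = length(universe),
    top = top
  ), class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("Overlap partition over %d samples (%d positions in union)\n",
              length(x$sample_ids), x$universe_size))
  shown <- head(x$pattern_counts, x$top)
  for (i in seq_along(shown)) {
    members <- x$sample_ids[strsplit(names(shown)[i], "")[[1]] == "1"]
    cat(sprintf("  %s  %6d   {%s}\n", names(shown)[i], shown[i],
                paste(members, collapse = ", ")))
  }
  rest <- sum(x$pattern_counts) - sum(shown)
  if (rest > 0) cat(sprintf("  (remainder: %d positions in %d further patterns)\n",
                            rest, length(x$pattern_counts) - x$top))
  invisible(x)
}

#' Plot an overlap partition as matrix-and-bars
#'
#' A minimal UpSet-style rendering: pattern bars on top, membership dots
#' below.
#' @param x an `overlap_partition`.
#' @param ... ignored.
#' @export
plot.overlap_partition <- function(x, ...) {
  shown <- head(x$pattern_counts, x$top)
  ns <- length(x$sample_ids)
  old <- graphics::par(mar = c(1, 8, 2, 1), mfrow = c(2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(shown, names.arg = rep("", length(shown)),
                    ylab = "positions", main = "Shared bi-allelic positions")
  graphics::plot(NULL, xlim = c(0.5, length(shown) + 0.5), ylim = c(0.5, ns + 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(ns), labels = rev(x$sample_ids), las = 2)
  for (i in seq_along(shown)) {
    bits <- strsplit(names(shown)[i], "")[[1]] == "1"
    graphics::points(rep(i, ns), rev(seq_len(ns)), pch = 21,
                     bg = ifelse(bits, "black", "white"))
  }
  invisible(x)
}

#' Helper: position keys for set operations
#'
#' @param calls classified site table.
#' @param class restrict to this classification (default `"bi"`).
#' @return character vector of `"contig:pos"` keys.
#' @export
position_keys <- function(calls, class = "bi") {
  sub <- calls[calls$class == class, , drop = FALSE]
  paste0(sub$contig, ":", sub$pos)
}

#' Cumulative hypergeometric overlap test
#'
#' Upper-tail (inclusive) probability of drawing at least `x` marked
#' positions: with `K` positions bi-allelic in sample A out of a universe of
#' `N` eligible positions, and `n` bi-allelic in sample B,
#' `p = P(X >= x)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N universe size (positions eligible in both samples).
#' @param K set-A size. @param n set-B size. @param x overlap.
#' @return list of class `overlap_test`: `N`, `K`, `n`, `x`, `p_value`.
#' @export
hypergeometric_overlap <- function(N, K, n, x) {
  if (K > N || n > N || x > min(K, n) || any(c(N, K, n, x) < 0)) {
    stop("impossible configuration: need 0 <= x <= min(K, n) <= N")
  }
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, x = x, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Cumulative hypergeometric overlap test\n  universe N = %d, |A| = %d, |B| = %d, overlap = %d\n  P(X >= %d) = %.4g\n",
    x$N, x$K, x$n, x$x, x$x, x$p_value))
  invisible(x)
}

#' RNA-to-genome allele-composition consistency
#'
#' A bi-allelic position detected in RNA-seq is *consistent* when the
#' whole-genome call at the same coordinate is bi-allelic with the identical
#' unordered allele pair; anything else (mono, different pair, tri-allelic,
#' missing or low-depth) is *inconsistent* — either a divergent allele
#' composition or a position not bi-allelic in WG data.
#'
#' @param rna_sites data.frame with `contig`, `pos` (0-based) and `alleles`
#'   (slash-joined pair, e.g. `"A/G"`).
#' @param wg_calls classified WG site table.
#' @param genome optional named character vector for bounds checking.
#' @return list: `table` (rna_sites + `wg_class`, `wg_alleles`, `status`),
#'   `n_consistent`, `n_inconsistent`.
#' @export
rna_wg_consistency <- function(rna_sites, wg_calls, genome = NULL) {
  if (!is.null(genome) && nrow(rna_sites) > 0) {
    lim <- nchar(genome)[rna_sites$contig]
    if (any(is.na(lim)) || any(rna_sites$pos < 0 | rna_sites$pos >= lim)) {
      stop("RNA position outside genome bounds")
    }
  }
  key_rna <- paste0(rna_sites$contig, ":", rna_sites$pos)
  key_wg <- paste0(wg_calls$contig, ":", wg_calls$pos)
  idx <- match(key_rna, key_wg)
  wg_class <- ifelse(is.na(idx), "NA", wg_calls$class[idx])
  wg_alleles <- ifelse(is.na(idx), "", wg_calls$alleles[idx])
  norm <- function(a) {
    vapply(strsplit(a, "/", fixed = TRUE),
           function(v) paste(sort(v), collapse = "/"), "")
  }
  consistent <- wg_class == "bi" & norm(wg_alleles) == norm(rna_sites$alleles)
  out <- rna_sites
  out$wg_class <- wg_class
  out$wg_alleles <- wg_alleles
  out$status <- ifelse(consistent, "consistent", "inconsistent")
  list(table = out,
       n_consistent = sum(consistent),
       n_inconsistent = sum(!consistent))
}
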