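# Insect survival statistic, pedigree numerator relationship matrix and
# trait correlations.

#' Insect survival percentage (NTS)
#'
#' `NTS = living / total_infested * 100`, reported to one decimal place.
#' With the standard infestation rate of 6 insects per plant the statistic
#' takes the discrete values 0, 16.7, 33.3, 50, 66.7, 83.3, 100.
#'
#' @param living number of living insects (nymphal + adult) at scoring;
#'   vectorized.
#' @param total_infested number of insects the plant was infested with
#'   (default 6).
#' @return Survival percentage(s) in \[0, 100\], rounded to one decimal.
#' @export
nts <- function(living, total_infested = 6L) {
  total_infested <- rep_len(total_infested, length(living))
  if (any(total_infested <= 0)) {
    stop("total_infested must be > 0", call. = FALSE)
  }
  if (any(living < 0 | living > total_infested, na.rm = TRUE)) {
    stop("living counts must lie in [0, total_infested]", call. = FALSE)
  }
  round(100 * living / total_infested, 1)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix A by the recursive tabular
#' rules: for individual j with parents (s, d),
#' `a_ij = (a_is + a_id) / 2` for previously processed i, and
#' `a_jj = 1 + a_sd / 2`. Unknown parents (`NA`, `""` or `"0"`) are
#' treated as unrelated, non-inbred founders. The pedigree must be
#' acyclic; rows are sorted topologically internally.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam`.
#' @return An object of class `pedigree_matrix` with `ids` and the
#'   symmetric matrix `A`.
#' @export
build_pedigree_A <- function(pedigree) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(pedigree))) {
    stop("pedigree must have columns id, sire, dam", call. = FALSE)
  }
  ids <- as.character(pedigree$id)
  if (anyDuplicated(ids)) stop("duplicated pedigree ids", call. = FALSE)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0") | is.na(x)] <- NA_character_
    x
  }
  sire <- clean(pedigree$sire)
  dam <- clean(pedigree$dam)
  known <- c(sire, dam)
  unknown_parents <- setdiff(known[!is.na(known)], ids)
  if (length(unknown_parents) > 0) {
    stop("parent id(s) not in pedigree and not marked as founders: ",
         paste(unknown_parents, collapse = ", "), call. = FALSE)
  }
  n <- length(ids)
  # topological sort: parents before offspring
  si <- match(sire, ids); di <- match(dam, ids)
  order_idx <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_idx) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ids[!placed], collapse = ", "), call. = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in order_idx) {
    s <- si[j]; d <- di[j]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[j, j] <- 1 + a_sd / 2
    for (i in order_idx) {
      if (i == j) break
      a_is <- if (!is.na(s)) A[i, s] else 0
      a_id <- if (!is.na(d)) A[i, d] else 0
      A[i, j] <- A[j, i] <- (a_is + a_id) / 2
    }
  }
  structure(list(ids = ids, A = A), class = "pedigree_matrix")
}

#' @export
print.pedigree_matrix <- function(x, ...) {
  cat(sprintf("<pedigree_matrix> %d individuals, mean diagonal %.3f\n",
              length(x$ids), mean(diag(x$A))))
  invisible(x)
}

#' Pairwise Pearson correlations among genotype-value traits
#'
#' Pairwise-complete Pearson correlations with two-sided p-values, as
#' applied to BLUEs (shrinkage-free genotype values). A constant trait
#' yields `NA`, not zero.
#'
#' @param blues data frame or matrix of per-genotype trait values (one
#'   column per trait); non-numeric columns (e.g. `genotype`) are dropped.
#' @return A list with matrices `r`, `p` and `n` (pairwise complete
#'   sample sizes).
#' @export
trait_correlations <- function(blues) {
  if (is.data.frame(blues)) {
    blues <- blues[vapply(blues, is.numeric, logical(1))]
    blues <- as.matrix(blues)
  }
  k <- ncol(blues)
  if (nrow(blues) < 3L) stop("need >= 3 genotypes", call. = FALSE)
  r <- p <- nmat <- matrix(NA_real_, k, k,
                           dimnames = list(colnames(blues), colnames(blues)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- complete.cases(blues[, c(i, j)])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3L || sd(blues[ok, i]) == 0 || sd(blues[ok, j]) == 0) next
      ct <- cor.test(blues[ok, i], blues[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nmat)
}
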