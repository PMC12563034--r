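# Correspondence analysis of the SOC-by-drug contingency table, built
# directly on the singular value decomposition of the chi-square
# standardized residual matrix, with contribution-biplot coordinates,
# dimension retention and top-variable selection.

#' Correspondence analysis of a contingency table
#'
#' Decomposes the association structure of a SOC-by-drug count table.
#' With correspondence matrix `P = O/n`, row masses `r` and column masses
#' `c`, the standardized residual matrix
#' `S[i,j] = (P[i,j] - r_i c_j) / sqrt(r_i c_j)` is factored by SVD,
#' `S = U diag(sigma) V'`. Squared singular values are the principal
#' inertias; their sum equals the table's Pearson chi-square statistic
#' divided by `n` (the total inertia). Principal coordinates are
#' `F = diag(r)^(-1/2) U diag(sigma)` for rows (SOCs) and
#' `G = diag(c)^(-1/2) V diag(sigma)` for columns (drugs); the chi-square
#' distance between two row profiles equals the Euclidean distance between
#' their principal coordinates. The contribution of row `i` to dimension
#' `k` is `r_i F[i,k]^2 / lambda_k = U[i,k]^2` (columns analogously), so
#' per-dimension contributions sum to one.
#'
#' In the contribution biplot rendering, drugs are plotted as points in
#' principal coordinates and SOCs as vectors in contribution coordinates
#' (`biplot = U`, the standard coordinates scaled by the square root of the
#' mass), so that a vector's squared coordinate on an axis is exactly its
#' contribution to that axis: the longer the vector, the more the SOC
#' drives the displayed separation.
#'
#' The SVD sign indeterminacy is resolved by forcing the largest-magnitude
#' row loading of each dimension positive, so coordinates are reproducible.
#'
#' @param x A `contingency_table` or count matrix with at least two rows,
#'   two columns, positive grand total and no zero margins
#'   (see [drop_zero_margins()]).
#' @return A `ca_result`: list with `sv` (singular values), `inertia`,
#'   `inertia_share`, `total_inertia`, `row_coord`, `col_coord`,
#'   `row_contrib`, `col_contrib`, `biplot`, `row_mass`, `col_mass`,
#'   `socs`, `drugs`. All matrices have `min(I, J) - 1` columns named
#'   `dm1`, `dm2`, ...
#' @export
#' @examples
#' tab <- matrix(c(30, 10, 5, 10, 30, 5, 5, 5, 30), 3,
#'               dimnames = list(c("Gastr", "Nerv", "Inv"), c("a", "b", "c")))
#' fit <- fit_ca(tab)
#' fit$inertia_share
fit_ca <- function(x) {
  table <- as_contingency_table(x)
  O <- table$counts
  if (nrow(O) < 2 || ncol(O) < 2) {
    stop("fit_ca: need at least a 2 x 2 table", call. = FALSE)
  }
  if (table$n <= 0) stop("fit_ca: empty table", call. = FALSE)
  if (any(table$row_totals == 0) || any(table$col_totals == 0)) {
    stop("fit_ca: zero-margin row or column; drop_zero_margins() first",
         call. = FALSE)
  }
  P <- O / table$n
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  dec <- svd(S)
  K <- min(nrow(O), ncol(O)) - 1  # nontrivial dimensions
  sigma <- dec$d[seq_len(K)]
  U <- dec$u[, seq_len(K), drop = FALSE]
  V <- dec$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {  # reproducible sign: top |loading| positive
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  lambda <- sigma^2
  total <- sum(lambda)
  dims <- paste0("dm", seq_len(K))
  F <- sweep(U, 2, sigma, `*`) / sqrt(r)
  G <- sweep(V, 2, sigma, `*`) / sqrt(c)
  dimnames(F) <- list(table$socs, dims)
  dimnames(G) <- list(table$drugs, dims)
  ctr_row <- U^2; dimnames(ctr_row) <- dimnames(F)
  ctr_col <- V^2; dimnames(ctr_col) <- dimnames(G)
  B <- U; dimnames(B) <- dimnames(F)
  structure(
    list(sv = stats::setNames(sigma, dims),
         inertia = stats::setNames(lambda, dims),
         inertia_share = stats::setNames(
           if (total > 0) lambda / total else rep(0, K), dims),
         total_inertia = total,
         row_coord = F, col_coord = G,
         row_contrib = ctr_row, col_contrib = ctr_col,
         biplot = B,
         row_mass = stats::setNames(r, table$socs),
         col_mass = stats::setNames(c, table$drugs),
         socs = table$socs, drugs = table$drugs),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("Correspondence analysis: %d SOCs x %d drugs, total inertia %.6g\n",
              length(x$socs), length(x$drugs), x$total_inertia))
  print(round(rbind(singular_value = x$sv,
                    inertia = x$inertia,
                    share = x$inertia_share), 4))
  invisible(x)
}

#' Number of dimensions to retain
#'
#' Average-inertia rule: with `K` nontrivial dimensions, a dimension is
#' worth interpreting when its inertia share exceeds `1/K`, the share it
#' would hold if inertia were spread uniformly. The count of such
#' dimensions is floored at two (a biplot needs two axes) and capped at
#' `K`.
#'
#' @param result A `ca_result`.
#' @return Integer number of retained dimensions.
#' @export
retain_dimensions <- function(result) {
  stopifnot(inherits(result, "ca_result"))
  K <- length(result$sv)
  keep <- sum(result$inertia_share > 1 / K)
  as.integer(min(max(keep, 2L), K))
}

#' Select the SOC variables that drive the retained dimensions
#'
#' Aggregates each SOC's per-dimension contributions over the retained
#' dimensions with inertia weights,
#' `agg_i = sum_k lambda_k ctr[i,k] / sum_k lambda_k`, flags SOCs whose
#' aggregated contribution exceeds the uniform-contribution threshold
#' `1/I` (the reciprocal of the number of SOC variables analyzed), and
#' ranks the top `top_n` (ties broken lexicographically on the SOC code).
#'
#' @param result A `ca_result`.
#' @param dims Number of leading dimensions to aggregate over; defaults to
#'   [retain_dimensions()].
#' @param top_n How many top variables to report (default 5; clamped to the
#'   number of SOCs with a warning).
#' @return A `variable_selection`: list with `threshold`, `contributions`
#'   (tibble `soc`, `contribution`, `selected`), `selected`, `top`.
#' @export
select_variables <- function(result, dims = retain_dimensions(result),
                             top_n = 5) {
  stopifnot(inherits(result, "ca_result"))
  K <- length(result$sv)
  if (dims > K) {
    stop("select_variables: dims exceeds available dimensions", call. = FALSE)
  }
  I <- length(result$socs)
  if (top_n > I) {
    warning("select_variables: top_n clamped to the number of SOCs (",
            I, ")", call. = FALSE)
    top_n <- I
  }
  lam <- result$inertia[seq_len(dims)]
  agg <- if (sum(lam) > 0) {
    as.vector(result$row_contrib[, seq_len(dims), drop = FALSE] %*% lam) / sum(lam)
  } else {
    rep(0, I)
  }
  threshold <- 1 / I
  ord <- order(-agg, result$socs)
  contributions <- tibble::tibble(
    soc = result$socs[ord],
    contribution = agg[ord],
    selected = agg[ord] > threshold
  )
  structure(
    list(threshold = threshold,
         contributions = contributions,
         selected = contributions$soc[contributions$selected],
         top = contributions$soc[seq_len(top_n)]),
    class = "variable_selection"
  )
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("Variable selection: threshold 1/I = %.4f; %d SOC(s) above it\n",
              x$threshold, length(x$selected)))
  print(x$contributions, n = 10)
  invisible(x)
}

#' Pairwise drug-profile distances in the retained subspace
#'
#' Euclidean distances between drug principal coordinates on the retained
#' dimensions, in ascending order: the closer two drugs, the more similar
#' their SOC reporting profiles.
#'
#' @param result A `ca_result`.
#' @param dims Number of leading dimensions to use; defaults to
#'   [retain_dimensions()].
#' @return A tibble with columns `drug_a`, `drug_b`, `distance`, ascending.
#' @export
profile_distance_ranking <- function(result,
                                     dims = retain_dimensions(result)) {
  stopifnot(inherits(result, "ca_result"))
  G <- result$col_coord[, seq_len(dims), drop = FALSE]
  d <- as.matrix(stats::dist(G))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble::tibble(
    drug_a = rownames(d)[pairs[, 1]],
    drug_b = colnames(d)[pairs[, 2]],
    distance = d[pairs]
  )
  dplyr::arrange(out, .data$distance)
}

#' Export CA coordinates for a contribution biplot
#'
#' Drugs as points (principal coordinates), SOCs as vectors (contribution
#' coordinates), over the first `dims` dimensions, with per-dimension
#' contributions and masses — everything a plotting layer needs.
#'
#' @param result A `ca_result`.
#' @param dims Number of dimensions to export (default 2).
#' @return A tibble with columns `entity`, `type` (`point`/`vector`),
#'   `dm1`..., `contribution_dm1`..., `mass`.
#' @export
ca_coordinates <- function(result, dims = 2) {
  stopifnot(inherits(result, "ca_result"))
  dims <- min(dims, length(result$sv))
  idx <- seq_len(dims)
  coord_cols <- function(m) {
    out <- tibble::as_tibble(m[, idx, drop = FALSE])
    names(out) <- paste0("dm", idx)
    out
  }
  ctr_cols <- function(m) {
    out <- tibble::as_tibble(m[, idx, drop = FALSE])
    names(out) <- paste0("contribution_dm", idx)
    out
  }
  drugs <- dplyr::bind_cols(
    tibble::tibble(entity = result$drugs, type = "point"),
    coord_cols(result$col_coord), ctr_cols(result$col_contrib),
    tibble::tibble(mass = unname(result$col_mass)))
  socs <- dplyr::bind_cols(
    tibble::tibble(entity = result$socs, type = "vector"),
    coord_cols(result$biplot), ctr_cols(result$row_contrib),
    tibble::tibble(mass = unname(result$row_mass)))
  dplyr::bind_rows(drugs, socs)
}

#' Export the inertia spectrum
#'
#' @param result A `ca_result`.
#' @return A tibble with columns `dim`, `singular_value`, `inertia`,
#'   `share`, `cumulative`.
#' @export
ca_inertia <- function(result) {
  stopifnot(inherits(result, "ca_result"))
  tibble::tibble(
    dim = names(result$sv),
    singular_value = unname(result$sv),
    inertia = unname(result$inertia),
    share = unname(result$inertia_share),
    cumulative = cumsum(unname(result$inertia_share))
  )
}
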