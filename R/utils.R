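#' @importFrom rlang abort warn %||%
#' @importFrom stats median mad rexp rnorm runif rpois setNames quantile ks.test ecdf
#' @importFrom utils head tail
NULL

# Exact box-filter local means via summed-area tables. Windows that overhang
# the image are clipped and renormalised by the true pixel count, so border
# means are unbiased.
box_sum <- function(x, side) {
  stopifnot(side %% 2 == 1, side >= 1)
  storage.mode(x) <- "double"   # integer input overflows the summed-area table
  n <- nrow(x); m <- ncol(x)
  r <- (side - 1L) / 2L
  S <- matrix(0, n + 1L, m + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(n); j <- seq_len(m)
  lo_i <- pmax(i - r, 1L); hi_i <- pmin(i + r, n)
  lo_j <- pmax(j - r, 1L); hi_j <- pmin(j + r, m)
  sums <- S[hi_i + 1L, hi_j + 1L] - S[lo_i, hi_j + 1L] -
    S[hi_i + 1L, lo_j] + S[lo_i, lo_j]
  counts <- outer(hi_i - lo_i + 1L, hi_j - lo_j + 1L)
  list(sum = sums, count = counts)
}

box_mean <- function(x, side) {
  b <- box_sum(x, side)
  b$sum / b$count
}

# Local variance over the same clipped box window (population variance).
# Values below the cancellation noise of the two-moment formula are exactly
# zero, so smooth regions stay silent under relative thresholds.
box_var <- function(x, side) {
  b1 <- box_sum(x, side)
  b2 <- box_sum(x * x, side)
  mu <- b1$sum / b1$count
  m2 <- b2$sum / b2$count
  v <- pmax(m2 - mu * mu, 0)
  v[v < 1e-9 * m2] <- 0
  v
}

# Binary disc kernel: pixel offsets with centre distance <= radius.
disc_kernel <- function(radius) {
  r <- max(1L, as.integer(radius))
  d <- seq(-r, r)
  k <- outer(d, d, function(a, b) a * a + b * b) <= radius * radius
  storage.mode(k) <- "integer"
  k
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonal-touching
# 4-components are merged through an igraph component pass.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl == 0L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    cbind(a[keep], b[keep])
  }
  e <- rbind(
    pairs(lab[-n, -m], lab[-1L, -1L]),  # down-right diagonal
    pairs(lab[-1L, -m], lab[-n, -1L])   # up-right diagonal
  )
  if (nrow(e) > 0L) {
    g <- igraph::graph_from_edgelist(unique(e), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nl - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    lab[lab > 0L] <- memb[lab[lab > 0L]]
  }
  lab
}

# Relabel a component image so labels run 1..k ordered by each component's
# lexicographically smallest (row, col) pixel, 0-based coordinates.
relabel_by_first_pixel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab)
  cols <- (idx - 1L) %/% nrow(lab)
  key <- rows * ncol(lab) + cols           # lexicographic (row, col)
  first <- tapply(key, lab[idx], min)
  ord <- ids[order(first[as.character(ids)])]
  map <- integer(max(ids)); map[ord] <- seq_along(ord)
  lab[idx] <- map[lab[idx]]
  lab
}

# Two-sample Kolmogorov-Smirnov statistic (sup-norm ECDF distance).
ks_statistic <- function(x, y) {
  n <- length(x); m <- length(y)
  stopifnot(n > 0, m > 0)
  w <- c(x, y)
  o <- order(w)
  step <- ifelse(o <= n, 1 / n, -1 / m)
  z <- cumsum(step)
  keep <- c(diff(w[o]) != 0, TRUE)   # evaluate at the end of tied runs
  max(abs(z[keep]))
}

md5_of_file <- function(path) unname(tools::md5sum(path))

assert_finite_matrix <- function(x, what = "image") {
  if (!all(is.finite(x))) abort(sprintf("%s contains non-finite pixels", what))
  invisible(x)
}
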