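# Internal array utilities shared across modules.

# Face-connected (6-neighbour) component labelling of a logical 3D array.
# Returns an integer array: 0 outside the mask, component id inside.
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lin <- which(mask)
  lab <- array(0L, dim = d)
  if (length(lin) == 0L) return(lab)
  map <- integer(prod(d))
  map[lin] <- seq_along(lin)

  idx <- arrayInd(lin, d)
  edges <- NULL
  for (ax in 1:3) {
    keep <- idx[, ax] < d[ax]
    nb <- lin[keep] + c(1L, d[1], d[1] * d[2])[ax]
    ok <- mask[nb]
    if (any(ok)) {
      edges <- rbind(edges, cbind(map[lin[keep][ok]], map[nb[ok]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[lin] <- as.integer(memb)
  lab
}

n_components <- function(mask) {
  lab <- label_components(mask)
  length(unique(lab[lab > 0L]))
}

# Erode a logical 3D array once with the 6-neighbour (face) structuring
# element: a voxel survives iff all six face neighbours are inside the mask
# (out-of-grid counts as outside).
erode_face <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift_ax <- function(m, ax, by) {
    res <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    res[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (ax in 1:3) {
    out <- out & shift_ax(mask, ax, 1L) & shift_ax(mask, ax, -1L)
  }
  out
}

# Running (box) sum of length k (odd) along each of the three axes, i.e. the
# sum of `arr` over a k x k x k cube centred at each voxel, with zero padding
# at the grid boundary. Implemented with cumulative sums; O(N) per axis.
box_sum_3d <- function(arr, k) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(arr)
  h <- (k - 1L) %/% 2L
  d <- dim(arr)
  run1 <- function(mat) {
    # running sum of window k down the rows of a matrix, zero-padded
    n <- nrow(mat)
    cs <- matrix(cumsum(mat), nrow = n)             # per-column + carry-over
    carry <- c(0, cs[n, -ncol(mat)])                # totals of previous cols
    cs <- sweep(cs, 2L, carry)                      # true per-column cumsums
    top <- pmin(seq_len(n) + h, n)
    bot <- seq_len(n) - h - 1L
    res <- cs[top, , drop = FALSE]
    pos <- bot >= 1L
    res[pos, ] <- res[pos, , drop = FALSE] - cs[bot[pos], , drop = FALSE]
    res
  }
  along <- function(a, ax) {
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- run1(matrix(ap, nrow = dp[1]))
    aperm(array(m, dim = dp), order(perm))
  }
  out <- arr
  for (ax in 1:3) out <- along(out, ax)
  out
}

# Deterministic per-task seed derived from a master seed, a text label and an
# index; always a positive integer below 2^31.
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (cc in utf8ToInt(as.character(label))) h <- (h * 131 + cc) %% 1000003
  as.integer(((abs(master) %% 100000) * 19997 + h * 977 + index * 7919) %%
               2147483629 + 1)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
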