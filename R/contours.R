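# Connected components and boundary tracing on logical masks.
# Coordinates everywhere: (x = column - 1, y = row - 1), y increasing
# downwards, matching the image convention used by the front types.

# 4-connected components of TRUE pixels; returns integer label matrix (0 for
# FALSE pixels). igraph does the union-find.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  # horizontal and vertical adjacency between TRUE pixels
  # mask[, -W] has nrow H, so its col-major ids coincide with the full matrix
  right <- which(mask[, -W, drop = FALSE] & mask[, -1L, drop = FALSE])
  down <- which(mask[-H, , drop = FALSE] & mask[-1L, , drop = FALSE])
  # ids in the full matrix: element (r, c) of the (H-1) x W slice is r + (c-1)*H
  dr <- (down - 1L) %% (H - 1L) + 1L
  dc <- (down - 1L) %/% (H - 1L) + 1L
  dfull <- dr + (dc - 1L) * H
  edges <- rbind(cbind(right, right + H), cbind(dfull, dfull + 1L))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2L),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(idx),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  ids <- as.integer(igraph::V(g)$name)
  lab[ids] <- comp$membership
  lab
}

# Moore-neighbour boundary tracing of the TRUE region given by `comp` (one
# connected component). Returns a k x 2 matrix of 0-based (x, y) boundary
# pixel coordinates in traversal order (closed: last step returns towards the
# first point). Single-pixel components yield one point.
trace_boundary <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  inside <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && comp[r, c]
  # start: topmost then leftmost TRUE pixel (row-major scan)
  idx <- which(comp)
  rr <- (idx - 1L) %% H + 1L; cc <- (idx - 1L) %/% H + 1L
  o <- order(rr, cc)
  sr <- rr[o[1L]]; sc <- cc[o[1L]]
  if (length(idx) == 1L) return(matrix(c(sc - 1L, sr - 1L), ncol = 2L,
                                       dimnames = list(NULL, c("x", "y"))))
  # clockwise neighbour order starting west: W, NW, N, NE, E, SE, S, SW
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  path_r <- integer(0); path_c <- integer(0)
  r <- sr; c <- sc
  # row-major scan reached start from its west neighbour, so pretend we moved
  # east (index 5) onto it: the backtrack pixel is then the west one
  dir_from <- 5L
  max_steps <- 4L * length(idx) + 8L
  first_move <- NULL
  for (step in seq_len(max_steps)) {
    path_r <- c(path_r, r); path_c <- c(path_c, c)
    found <- FALSE
    for (k in 0:7) {
      d <- (dir_from + 4L + 1L + k - 1L) %% 8L + 1L  # start after backtrack
      nr <- r + drs[d]; nc <- c + dcs[d]
      if (inside(nr, nc)) {
        if (!is.null(first_move) && r == sr && c == sc &&
            identical(c(nr, nc), first_move)) {
          return(cbind(x = path_c - 1L, y = path_r - 1L))
        }
        if (is.null(first_move)) first_move <- c(nr, nc)
        r <- nr; c <- nc; dir_from <- d
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated after all (shouldn't happen for |comp|>1)
  }
  cbind(x = path_c - 1L, y = path_r - 1L)
}

polyline_length <- function(pts, closed = TRUE) {
  if (nrow(pts) < 2L) return(0)
  d <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  len <- sum(d)
  if (closed) len <- len + sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2))
  len
}
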