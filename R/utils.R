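# Internal helpers: coordinate conventions, seeded RNG scoping, 8-connected
# labeling on top of EBImage's 4-connected bwlabel.
#
# Frames are numeric arrays dim = c(height, width, 3) with values in [0, 1].
# Pixel coordinates are 0-based, origin top-left, x right (column), y down
# (row), so pixel (x, y) lives at frame[y + 1, x + 1, ].

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif
NULL

.assertFrame <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be a height x width x 3 numeric array", call. = FALSE)
  invisible(frame)
}

.assertMask <- function(mask) {
  if (!is.matrix(mask))
    stop("mask must be a height x width matrix", call. = FALSE)
  invisible(mask)
}

# Evaluate expr with a local, reproducible RNG state; the caller's RNG
# state is untouched. `state` may be an integer scalar seed or a saved
# .Random.seed vector. Returns list(value, state) with the advanced state.
withRNG <- function(state, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  if (length(state) == 1L) set.seed(as.integer(state))
  else assign(".Random.seed", state, envir = env)
  value <- force(expr)
  list(value = value,
       state = get(".Random.seed", envir = env, inherits = FALSE))
}

# Derive a per-stream child seed from a base seed and a stream id, kept
# within 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally via union-find on the (small) label graph.
label8 <- function(mask) {
  .assertMask(mask)
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  remap <- c(0L, dense)
  matrix(remap[lab + 1L], nrow = nr)
}

# Integer pixel rectangle helpers. A rect is c(x0, y0, x1, y1), 0-based,
# inclusive. Width/height in pixels.
rectWidth  <- function(r) r[3] - r[1] + 1
rectHeight <- function(r) r[4] - r[2] + 1

# Clip rect to a frame of size dim = c(width, height); returns NULL when
# nothing remains.
clipRect <- function(r, frameDim) {
  out <- c(max(r[1], 0), max(r[2], 0),
           min(r[3], frameDim[1] - 1), min(r[4], frameDim[2] - 1))
  if (out[1] > out[3] || out[2] > out[4]) return(NULL)
  out
}

# Sum of a matrix over an integer rect (0-based, inclusive).
rectSum <- function(m, r) {
  sum(m[(r[2] + 1):(r[4] + 1), (r[1] + 1):(r[3] + 1)])
}
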