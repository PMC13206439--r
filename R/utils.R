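# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All user-facing randomness in the package flows through this.
withSeed <- function(seed, expr) {
    if (!is.null(old <- get0(".Random.seed", globalenv()))) {
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a child seed from a base seed, staying within 32-bit integer range.
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

emptyNoduleFrame <- function() {
    data.frame(xmin = numeric(0), ymin = numeric(0),
               xmax = numeric(0), ymax = numeric(0),
               areaPx = numeric(0), aspectRatio = numeric(0))
}

# Tight half-open bounding box of a set of foreground pixels given as
# (row, col) 1-based indices; returns 0-based half-open coordinates.
tightBox <- function(rows, cols) {
    c(xmin = min(cols) - 1, ymin = min(rows) - 1,
      xmax = max(cols), ymax = max(rows))
}

asBoxFrame <- function(x) {
    x <- as.data.frame(x)
    stopifnot(all(c("xmin", "ymin", "xmax", "ymax") %in% names(x)))
    x
}
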