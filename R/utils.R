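# Internal helpers shared across modules.

#' @importFrom rlang abort
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("mirrortree_input_error", "mirrortree_error"))
}

stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("mirrortree_degenerate_error", "mirrortree_error"))
}

# Evaluate `code` under a fixed RNG state when `seed` is given, otherwise use
# the current stream. Keeps user-level RNG state untouched when seeded.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Per-stage seed derivation from one master seed: documented, deterministic,
# and kept inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 10007 * as.double(offset)) %% 2147483646 + 1)
}

# Upper-triangle flattening used for both matrices of a matched pair: the
# ordering (column-major over i < j) is irrelevant in itself but must be the
# same for both families.
upper_tri_vec <- function(M) M[upper.tri(M)]

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Quote a label for newick if it contains structural characters.
newick_quote <- function(x) {
  needs <- grepl("[][():;,' \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

fmt_len <- function(x) formatC(x, digits = 17, format = "g")

check_distance_matrix <- function(D, arg = "D") {
  if (!is.matrix(D) || !is.numeric(D)) {
    stop_input("`%s` must be a numeric matrix", arg)
  }
  if (nrow(D) != ncol(D)) stop_input("`%s` must be square", arg)
  if (is.null(rownames(D))) stop_input("`%s` must carry organism labels as dimnames", arg)
  if (anyNA(D) || any(!is.finite(D))) stop_input("`%s` contains non-finite entries", arg)
  if (any(D < 0)) stop_input("`%s` contains negative distances", arg)
  if (any(abs(diag(D)) > 1e-12)) stop_input("`%s` must have a zero diagonal", arg)
  if (max(abs(D - t(D))) > 1e-12) stop_input("`%s` is not symmetric", arg)
  invisible(D)
}
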