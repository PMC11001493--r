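# Shared internal helpers: argument checks, seeded RNG scoping, matrix glue.

# Amino-acid alphabet: 20 standard residues plus ambiguity/rare codes.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
  "X", "B", "Z", "U", "O"
)

DEFAULT_THRESHOLDS <- c(40, 45, 50, 55, 60, 65)
EXTENDED_THRESHOLDS <- c(40, 45, 50, 55, 60, 65, 70, 75, 80)

#' Temperature threshold grids
#'
#' The default operating grid covers 40-65 degrees C in 5-degree steps (six
#' thresholds); the extended grid adds 70, 75 and 80 degrees C.
#'
#' @param mode `"default"` or `"extended"`.
#' @return Ascending numeric vector of thresholds in degrees C.
#' @examples
#' threshold_grid("default")
#' threshold_grid("extended")
#' @export
threshold_grid <- function(mode = c("default", "extended")) {
  mode <- match.arg(mode)
  if (mode == "default") DEFAULT_THRESHOLDS else EXTENDED_THRESHOLDS
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from (seed, salt) without touching RNG state.
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 1e6) * 1009 + as.double(salt) %% 1e6
  as.integer(s %% 2147483647)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number, got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_ascending <- function(thresholds, name = "thresholds") {
  if (length(thresholds) < 1L || anyNA(thresholds)) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort(sprintf("`%s` must be strictly ascending (got: %s).",
                  name, paste(thresholds, collapse = ", ")))
  }
  invisible(thresholds)
}

# Stack an `embedding` list-column into an N x D matrix with sequence_id rownames.
embedding_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  if (!is_tibble(data) && !is.data.frame(data)) {
    abort("Expected a data frame with an `embedding` list-column or a matrix.")
  }
  if (!"embedding" %in% names(data)) {
    abort("Data frame has no `embedding` list-column.")
  }
  d <- lengths(data$embedding)
  if (length(unique(d)) != 1L) {
    abort("All embedding vectors must share one dimension D.")
  }
  m <- do.call(rbind, data$embedding)
  if ("sequence_id" %in% names(data)) rownames(m) <- data$sequence_id
  m
}

# Coerce a single input vector or matrix of row-vectors to a matrix.
as_input_matrix <- function(x, input_dim) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x)) x <- embedding_matrix(x)
  if (ncol(x) != input_dim) {
    abort(sprintf("Input dimension mismatch: expected %d features, got %d.",
                  input_dim, ncol(x)))
  }
  if (!all(is.finite(x))) abort("Input contains non-finite values.")
  x
}

# Label column name for a threshold, e.g. label_40, label_62.5 -> "label_62.5".
label_col <- function(threshold) paste0("label_", format(threshold, trim = TRUE))

prob_col <- function(threshold) paste0("prob_", format(threshold, trim = TRUE))
call_col <- function(threshold) paste0("call_", format(threshold, trim = TRUE))
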