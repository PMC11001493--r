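#' Pool a per-residue embedding matrix to a mean vector
#'
#' The classifier's input representation is the column-wise arithmetic mean
#' of a protein's per-residue embedding matrix (L residues x D features).
#'
#' @param residue_matrix Numeric L x D matrix, L >= 1, finite entries.
#' @return Numeric vector of length D.
#' @examples
#' mean_pool(rbind(c(0, 0), c(2, 2)))
#' @export
mean_pool <- function(residue_matrix) {
  if (!is.matrix(residue_matrix) || nrow(residue_matrix) < 1L) {
    abort("`residue_matrix` must be a matrix with at least one row.")
  }
  if (!all(is.finite(residue_matrix))) {
    abort("`residue_matrix` contains non-finite entries.")
  }
  colMeans(residue_matrix)
}

#' Sliding-window (per-segment) pooling
#'
#' Averages every length-`k` window of consecutive residue rows (stride 1, no
#' partial windows at the edges), yielding one mean vector per segment — the
#' representation behind per-segment thermostability prediction.
#'
#' @inheritParams mean_pool
#' @param k Window size, `1 <= k <= L`.
#' @return An (L - k + 1) x D matrix; row i averages residue rows
#'   i..i+k-1 (1-based, inclusive).
#' @export
segment_pool <- function(residue_matrix, k) {
  if (!is.matrix(residue_matrix) || nrow(residue_matrix) < 1L) {
    abort("`residue_matrix` must be a matrix with at least one row.")
  }
  L <- nrow(residue_matrix)
  if (k < 1L) abort("Window size `k` must be >= 1.")
  if (k > L) {
    abort(sprintf("Window size k = %d exceeds sequence length L = %d.", k, L))
  }
  # cumulative sums give each window mean in O(L*D)
  cs <- apply(residue_matrix, 2L, cumsum)
  cs <- rbind(0, cs)
  out <- (cs[(k + 1L):(L + 1L), , drop = FALSE] -
            cs[1L:(L - k + 1L), , drop = FALSE]) / k
  dimnames(out) <- NULL
  out
}

#' Deterministic hash embedder (mock)
#'
#' A stand-in embedder for tests and offline runs: residue row i is a
#' pseudo-random vector with approximately zero mean and unit variance,
#' derived purely from (residue identity, position, seed). Identical inputs
#' give bit-identical matrices, and changing one residue changes only that
#' row.
#'
#' @param sequence Amino-acid string (or a one-row tibble with a `sequence`
#'   column).
#' @param D Embedding dimension (default 1024).
#' @param seed Integer seed.
#' @return L x D numeric matrix.
#' @export
hash_embed <- function(sequence, D = 1024L, seed = 1L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  if (D < 1L) abort("`D` must be >= 1.")
  s <- toupper(sequence)
  chars <- utf8ToInt(s)
  if (length(chars) == 0L) abort("Cannot embed an empty sequence.")
  rows <- lapply(seq_along(chars), function(i) {
    h <- (chars[i] * 2654435761 + i * 40503 + as.double(seed) * 97) %% 2147483647
    with_seed(as.integer(h), rnorm(D))
  })
  do.call(rbind, rows)
}

#' Adapter to a real pretrained protein language model
#'
#' The toolkit's embedder contract is pluggable; this adapter is the slot for
#' a pretrained transformer encoder (e.g. a ProtT5-class model) producing
#' last-layer per-residue hidden states. No encoder is bundled with the
#' package, so calling it without one configured raises an informative error;
#' everything else in the toolkit works with the mock embedders.
#'
#' @inheritParams hash_embed
#' @param encoder Optional function `sequence -> L x D matrix` wrapping an
#'   external encoder.
#' @return L x D numeric matrix of per-residue hidden states.
#' @export
plm_embed <- function(sequence, encoder = getOption("thermopred.plm_encoder")) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  if (is.null(encoder)) {
    abort(paste(
      "No pretrained protein-language-model encoder is configured.",
      "Set options(thermopred.plm_encoder = <function>) to plug one in,",
      "or use embedder = 'mock-hash' / 'mock-signal' for offline runs."))
  }
  m <- encoder(sequence)
  if (!is.matrix(m) || nrow(m) != nchar(sequence) || !all(is.finite(m))) {
    abort("Encoder must return a finite L x D matrix with one row per residue.")
  }
  m
}

#' Compute mean embeddings for a set of sequences
#'
#' Vectorized front-end over the embedder contract. `"mock-hash"` mean-pools
#' the deterministic hash embedder; `"mock-signal"` draws mean embeddings
#' from the synthetic OGT-signal model (requires `annotations`; see
#' [simulate_dataset()] for the model); `"plm"` routes through [plm_embed()].
#'
#' @param sequences Tibble with `id`, `sequence` and (for `"mock-signal"`)
#'   `organism_key`.
#' @param embedder One of `"mock-hash"`, `"mock-signal"`, `"plm"`.
#' @param D Embedding dimension.
#' @param seed Integer seed (mock embedders are pure functions of sequence,
#'   D and seed).
#' @param annotations Annotation tibble (`organism_key`,
#'   `growth_temperature`); required by `"mock-signal"`.
#' @param beta,sigma Signal strength and noise sd for `"mock-signal"`
#'   (see [simulate_dataset()]).
#' @return Tibble with `sequence_id` and an `embedding` list-column.
#' @export
embed_sequences <- function(sequences,
                            embedder = c("mock-hash", "mock-signal", "plm"),
                            D = 1024L, seed = 1L, annotations = NULL,
                            beta = 3, sigma = 1) {
  embedder <- match.arg(embedder)
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  emb <- switch(
    embedder,
    "mock-hash" = lapply(sequences$sequence, function(s) {
      mean_pool(hash_embed(s, D = D, seed = seed))
    }),
    "mock-signal" = {
      if (is.null(annotations)) {
        abort("embedder = 'mock-signal' requires `annotations`.")
      }
      ogt <- annotations$growth_temperature[
        match(sequences$organism_key, annotations$organism_key)]
      if (anyNA(ogt)) {
        bad <- unique(sequences$organism_key[is.na(ogt)])
        abort(sprintf("Missing growth-temperature annotation for organism(s): %s",
                      paste(head(bad, 5), collapse = ", ")))
      }
      signal_embed(sequences$id, ogt, D = D, seed = seed,
                   beta = beta, sigma = sigma)
    },
    "plm" = lapply(sequences$sequence, function(s) mean_pool(plm_embed(s)))
  )
  tibble(sequence_id = sequences$id, embedding = emb)
}
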