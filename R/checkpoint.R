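# Checkpoint container: a directory of text weight arrays plus a JSON
# metadata sidecar. "%.17g" formatting round-trips IEEE doubles bit-exactly,
# so load(save(model)) reproduces predictions exactly while staying diffable.

CHECKPOINT_FORMAT_VERSION <- "1.0"

write_array <- function(x, path) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(sprintf("%.17g", x[i, ]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
}

read_array <- function(path) {
  lines <- readr::read_lines(path)
  m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.double))
  if (nrow(m) == 1L) drop(m) else m
}

#' Save / load a classifier checkpoint
#'
#' A checkpoint is a directory holding one text file per weight array
#' (`W1.tsv`, `b1.tsv`, ...; 17-significant-digit decimal, bit-exact for
#' doubles) and a `meta.json` descriptor with the format version, the
#' architecture (input dimension, hidden sizes, activations) and training
#' metadata (threshold, seed, selected epoch, validation MCC). Loading
#' validates every array shape against the descriptor and refuses unknown
#' format versions, so a tampered or truncated checkpoint fails loudly.
#'
#' @param model A `thermo_mlp` model (see [train_classifier()], [init_mlp()]).
#' @param dir Checkpoint directory (created if needed).
#' @return `save_checkpoint()`: `dir`, invisibly. `load_checkpoint()`: the
#'   `thermo_mlp` model.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "thermo_mlp"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in seq_along(model$weights)) {
    write_array(model$weights[[l]]$W, file.path(dir, sprintf("W%d.tsv", l)))
    write_array(model$weights[[l]]$b, file.path(dir, sprintf("b%d.tsv", l)))
  }
  meta <- list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    spec = unclass(model$spec),
    meta = model$meta
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("Not a checkpoint directory (no meta.json): %s", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, CHECKPOINT_FORMAT_VERSION)) {
    abort(sprintf("Unknown checkpoint format version '%s' (supported: %s).",
                  meta$format_version, CHECKPOINT_FORMAT_VERSION))
  }
  spec <- mlp_spec(input_dim = meta$spec$input_dim, hidden = meta$spec$hidden)
  dims <- layer_dims(spec$input_dim, spec$hidden)
  weights <- vector("list", nrow(dims))
  for (l in seq_len(nrow(dims))) {
    W <- read_array(file.path(dir, sprintf("W%d.tsv", l)))
    b <- read_array(file.path(dir, sprintf("b%d.tsv", l)))
    if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
    if (!identical(dim(W), c(dims[l, 1L], dims[l, 2L])) ||
        length(b) != dims[l, 2L]) {
      abort(sprintf(
        "Checkpoint layer %d shape mismatch: descriptor says %dx%d (+%d bias), file has %dx%d (+%d).",
        l, dims[l, 1L], dims[l, 2L], dims[l, 2L],
        nrow(W), ncol(W), length(b)))
    }
    weights[[l]] <- list(W = W, b = as.double(b))
  }
  new_thermo_mlp(weights, spec, meta$meta)
}

layer_dims <- function(input_dim, hidden) {
  sizes <- c(input_dim, hidden, 1L)
  cbind(as.integer(sizes[-length(sizes)]), as.integer(sizes[-1L]))
}

#' Save / load a threshold ensemble
#'
#' An ensemble directory holds `ensemble.json` (threshold, member seeds) and
#' one checkpoint subdirectory per member. [save_ensemble_set()] writes one
#' ensemble directory per threshold (named `T<threshold>`) plus `set.json`.
#'
#' @param ensemble A `thermo_ensemble` (see [train_ensemble()]).
#' @param dir Directory.
#' @return Saving returns `dir` invisibly; loading returns the ensemble /
#'   named list of ensembles.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "thermo_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format_version = CHECKPOINT_FORMAT_VERSION,
         threshold = ensemble$threshold,
         member_seeds = ensemble$member_seeds),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(ensemble$members)) {
    save_checkpoint(ensemble$members[[i]],
                    file.path(dir, sprintf("member_%02d", i)))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  member_dirs <- sort(list.dirs(dir, recursive = FALSE))
  member_dirs <- member_dirs[grepl("member_\\d+$", member_dirs)]
  members <- lapply(member_dirs, load_checkpoint)
  new_thermo_ensemble(meta$threshold, members, meta$member_seeds)
}

#' @rdname save_ensemble
#' @param ensembles Named list of `thermo_ensemble` objects (one per
#'   threshold), as from [train_ensembles()].
#' @export
save_ensemble_set <- function(ensembles, dir) {
  thresholds <- vapply(ensembles, function(e) e$threshold, numeric(1))
  check_ascending(sort(thresholds))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format_version = CHECKPOINT_FORMAT_VERSION,
         thresholds = sort(thresholds)),
    file.path(dir, "set.json"), auto_unbox = TRUE, digits = NA)
  for (e in ensembles) {
    save_ensemble(e, file.path(dir, paste0("T", format(e$threshold, trim = TRUE))))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "set.json"), simplifyVector = TRUE)
  thresholds <- sort(meta$thresholds)
  ens <- lapply(thresholds, function(t) {
    load_ensemble(file.path(dir, paste0("T", format(t, trim = TRUE))))
  })
  names(ens) <- paste0("T", format(thresholds, trim = TRUE))
  ens
}
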