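# Synthetic-data generator: OGT-annotated organisms, random protein
# sequences, and mean embeddings carrying a controllable monotone
# thermostability signal, so the whole pipeline runs and is testable offline.

STANDARD_AA <- AA_ALPHABET[1:20]

# Fixed base vector mu and unit signal direction u, seeded.
signal_params <- function(D, seed) {
  with_seed(derive_seed(seed, 104729), {
    mu <- rnorm(D)
    u <- rnorm(D)
    list(mu = mu, u = u / sqrt(sum(u^2)))
  })
}

# Mean embedding model: x_i = mu + beta * ((t_i - 50)/50) * sqrt(D) * u + eps_i,
# eps elementwise N(0, sigma^2). With u a unit vector, u's entries are
# O(1/sqrt(D)), so the sqrt(D) factor makes beta the per-coordinate effect
# size at the OGT extremes relative to the per-coordinate noise sd sigma.
signal_embed <- function(ids, ogt, D, seed, beta = 3, sigma = 1) {
  p <- signal_params(D, seed)
  n <- length(ids)
  eps <- with_seed(derive_seed(seed, 7919),
                   matrix(rnorm(n * D, sd = sigma), nrow = n))
  coef <- beta * ((ogt - 50) / 50) * sqrt(D)
  x <- matrix(p$mu, nrow = n, ncol = D, byrow = TRUE) +
    outer(coef, p$u) + eps
  lapply(seq_len(n), function(i) x[i, ])
}

#' Simulate an OGT-annotated proteome with signal-bearing embeddings
#'
#' Generates `n_organisms` organisms with optimal growth temperatures drawn
#' from a chosen distribution, `proteins_per_organism` random amino-acid
#' sequences each, and one mean embedding per protein following
#' `x = mu + beta * ((OGT - 50)/50) * sqrt(D) * u + eps`, where `mu` is a
#' fixed seeded base vector, `u` a fixed seeded unit direction, and `eps`
#' elementwise Gaussian noise with sd `sigma`. The class signal is thus a
#' monotone (linear) function of OGT along a single direction, the simplest
#' model under which all per-threshold classifiers should be mutually
#' consistent — making the clash rate a meaningful test statistic. Sequence
#' content is decoupled from the embedding signal so classifier behaviour
#' can be tested in isolation from embedder behaviour.
#'
#' The two named OGT distributions emulate the temperature coverage of
#' training corpora built from sampled prokaryotic proteomes: `"bimodal"`
#' (mesophile/thermophile mixture, uniform on 20-40 or 60-80 with equal
#' weight) and `"uniform"` (full 0-100 coverage).
#'
#' @param n_organisms Number of organisms.
#' @param ogt `"uniform"`, `"bimodal"`, or a numeric vector of length
#'   `n_organisms` of fixed OGTs (degrees C).
#' @param proteins_per_organism Proteins simulated per organism.
#' @param length_range Integer `(min, max)` sequence length.
#' @param D Embedding dimension.
#' @param beta Per-coordinate signal strength at the OGT extremes (>= 0);
#'   `beta = 0` gives no class signal.
#' @param sigma Per-coordinate noise sd (> 0).
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   arguments.
#' @return An object of class `thermo_sim`: a list with tibbles `sequences`
#'   (`id`, `organism_key`, `sequence`), `annotations` (`organism_key`,
#'   `growth_temperature`) and `data` (`sequence_id`, `organism_key`,
#'   `growth_temperature`, `embedding` list-column), plus `direction` (u),
#'   `base` (mu) and `config`.
#' @examples
#' sim <- simulate_dataset(n_organisms = 20, D = 8, seed = 1)
#' sim$data
#' @export
simulate_dataset <- function(n_organisms = 3000,
                             ogt = c("uniform", "bimodal"),
                             proteins_per_organism = 1,
                             length_range = c(80, 300),
                             D = 128L, beta = 3, sigma = 1, seed = 1L) {
  stopifnot(n_organisms >= 1, proteins_per_organism >= 1,
            length_range[1] <= length_range[2], D >= 1, beta >= 0, sigma > 0)
  if (is.character(ogt)) ogt <- match.arg(ogt)
  temps <- with_seed(derive_seed(seed, 11), draw_ogt(ogt, n_organisms))
  ann <- tibble(
    organism_key = sprintf("org%05d", seq_len(n_organisms)),
    growth_temperature = temps
  )
  n_prot <- n_organisms * proteins_per_organism
  org_of <- rep(seq_len(n_organisms), each = proteins_per_organism)
  seqs <- with_seed(derive_seed(seed, 13), {
    lens <- sample(length_range[1]:length_range[2], n_prot, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(STANDARD_AA, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  sequences <- tibble(
    id = sprintf("prot%06d", seq_len(n_prot)),
    organism_key = ann$organism_key[org_of],
    sequence = seqs
  )
  gt <- ann$growth_temperature[org_of]
  emb <- signal_embed(sequences$id, gt, D = D, seed = seed,
                      beta = beta, sigma = sigma)
  p <- signal_params(D, seed)
  structure(list(
    sequences = sequences,
    annotations = ann,
    data = tibble(
      sequence_id = sequences$id,
      organism_key = sequences$organism_key,
      growth_temperature = gt,
      embedding = emb
    ),
    direction = p$u,
    base = p$mu,
    config = list(n_organisms = n_organisms, ogt = ogt,
                  proteins_per_organism = proteins_per_organism,
                  length_range = length_range, D = D, beta = beta,
                  sigma = sigma, seed = seed)
  ), class = "thermo_sim")
}

draw_ogt <- function(ogt, n) {
  if (is.numeric(ogt)) {
    if (length(ogt) != n) {
      abort(sprintf("Fixed OGT list has length %d but n_organisms = %d.",
                    length(ogt), n))
    }
    return(as.double(ogt))
  }
  switch(ogt,
    uniform = runif(n, 0, 100),
    bimodal = ifelse(runif(n) < 0.5, runif(n, 20, 40), runif(n, 60, 80))
  )
}

#' @export
print.thermo_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<thermo_sim> %d organisms x %d protein(s), D = %d, beta = %g, sigma = %g, seed = %s\n",
    cfg$n_organisms, cfg$proteins_per_organism, cfg$D, cfg$beta, cfg$sigma,
    cfg$seed))
  invisible(x)
}

#' Add homologous sequence families with known cluster truth
#'
#' Builds a family structure over a simulated dataset so cluster-aware
#' splitting can be exercised against known truth: each family consists of a
#' founder sequence (taken from the dataset) plus point-mutated copies
#' (`copies_per_family` members in total, founder included). Copies inherit
#' the founder's organism and OGT; their embeddings are drawn from the same
#' signal model with fresh noise. The returned ground-truth cluster table
#' maps family members together.
#'
#' @param sim A `thermo_sim` from [simulate_dataset()] with at least
#'   `n_families` proteins.
#' @param n_families Number of families.
#' @param copies_per_family Family size including the founder.
#' @param mutation_rate Per-position point-mutation probability in
#'   \[0, 0.7).
#' @param seed Integer seed.
#' @return A list with `sequences`, `data` (embeddings included) and the
#'   ground-truth cluster table `clusters` (`id`, `cluster`,
#'   `representative`).
#' @export
make_cluster_structure <- function(sim, n_families = 50,
                                   copies_per_family = 5,
                                   mutation_rate = 0.1, seed = 1L) {
  stopifnot(inherits(sim, "thermo_sim"))
  if (mutation_rate < 0 || mutation_rate >= 0.7) {
    abort("`mutation_rate` must be in [0, 0.7).")
  }
  if (nrow(sim$sequences) < n_families) {
    abort(sprintf("Need >= %d proteins in `sim` for %d families.",
                  n_families, n_families))
  }
  founders <- sim$sequences[seq_len(n_families), ]
  members <- with_seed(derive_seed(seed, 17), {
    purrr::map_dfr(seq_len(n_families), function(f) {
      founder <- founders[f, ]
      copies <- purrr::map_chr(seq_len(copies_per_family - 1L), function(j) {
        mutate_sequence(founder$sequence, mutation_rate)
      })
      tibble(
        id = c(founder$id,
               sprintf("%s_v%02d", founder$id, seq_len(copies_per_family - 1L))),
        organism_key = founder$organism_key,
        sequence = c(founder$sequence, copies),
        family = f
      )
    })
  })
  gt <- sim$annotations$growth_temperature[
    match(members$organism_key, sim$annotations$organism_key)]
  cfg <- sim$config
  emb <- signal_embed(members$id, gt, D = cfg$D,
                      seed = derive_seed(seed, 19),
                      beta = cfg$beta, sigma = cfg$sigma)
  list(
    sequences = members[c("id", "organism_key", "sequence")],
    data = tibble(
      sequence_id = members$id,
      organism_key = members$organism_key,
      growth_temperature = gt,
      embedding = emb
    ),
    clusters = tibble(
      id = members$id,
      cluster = members$family - 1L,
      representative = !grepl("_v\\d+$", members$id)
    )
  )
}

mutate_sequence <- function(s, rate) {
  if (rate == 0) return(s)
  chars <- strsplit(s, "")[[1L]]
  hit <- which(rbinom(length(chars), 1L, rate) == 1L)
  for (i in hit) {
    chars[i] <- sample(setdiff(STANDARD_AA, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}
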