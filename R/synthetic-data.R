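# Synthetic cohort generator: plants a low-rank nonnegative signature
# structure with group-specific dominant signatures, then renders observed
# abundances with multiplicative lognormal noise. The default profile mirrors
# the study design this package targets: 283 polar metabolites measured in
# 15 animals, 8 in condition group A and 7 in group B, with 5 latent
# metabolic signatures.

# Which signatures dominate each group. With five or more signatures the
# third and fifth are designated (group A resp. B), echoing the S3/S5 layout
# of the motivating cohort; with fewer, the first and last distinct pair.
dominant_signatures <- function(k) {
  if (k >= 5L) c(a = 3L, b = 5L)
  else if (k >= 2L) c(a = 1L, b = k)
  else c(a = 1L, b = 1L)
}

#' Generate planted ground truth for a synthetic metabolomics cohort
#'
#' Draws `n_signatures` column-stochastic metabolite signatures from a sparse
#' symmetric Dirichlet and plants a weight structure with one designated
#' dominant signature per condition group. Base exposures are heavy-tailed
#' (clipped Gamma), so each shared signature is anchored by a few
#' high-exposure samples — the situation that makes latent metabolic programs
#' discoverable in a small cohort. At separation `s`, each group's designated
#' signature gains an extra weight of `1.5 * s` (jittered) in its own group
#' while its base exposure is damped by `0.2^s` everywhere, i.e. the program
#' runs strongly in its group and at floor level in the other. The group
#' label never enters the base sampler, so at `separation = 0` the two
#' groups are exchangeable by construction.
#'
#' @param n_metabolites,n_group_a,n_group_b,n_signatures positive integers.
#'   Defaults give the 283-metabolite, 8 + 7 sample, 5-signature profile.
#' @param separation nonnegative real controlling how strongly the groups
#'   favor their designated signatures (0 = no group structure).
#' @param noise_sigma log-scale standard deviation of the multiplicative
#'   noise applied by [render_matrix()].
#' @param dirichlet_alpha concentration of the signature Dirichlet; small
#'   values give sparse signatures.
#' @param exposure_clip upper bound on a base exposure; keeps anchor samples
#'   from dwarfing the group-dominant program in any profile.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return an object of class `SyntheticGroundTruth` with elements
#'   `true_signatures` (M x K, columns sum to 1), `true_weights` (K x N),
#'   `group_labels`, `metabolite_ids`, `sample_ids`, `dominant`,
#'   `noise_sigma`, `separation`, `seed`.
#' @export
generate_ground_truth <- function(n_metabolites = 283, n_group_a = 8,
                                  n_group_b = 7, n_signatures = 5,
                                  separation = 2.0, noise_sigma = 0.1,
                                  dirichlet_alpha = 0.1, exposure_clip = 2.5,
                                  seed = 1) {
  m <- check_count(n_metabolites, "n_metabolites")
  na <- check_count(n_group_a, "n_group_a")
  nb <- check_count(n_group_b, "n_group_b")
  k <- check_count(n_signatures, "n_signatures")
  n <- na + nb
  if (k > min(m, n)) {
    stop("invalid parameter: `n_signatures` exceeds min(n_metabolites, n_samples)",
         call. = FALSE)
  }
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    stop("invalid parameter: `separation` must be a nonnegative real", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("invalid parameter: `noise_sigma` must be >= 0", call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)

  group_labels <- c(rep("A", na), rep("B", nb))
  dom <- dominant_signatures(k)

  out <- with_seed(derive_seed(seed, "ground_truth"), {
    # sparse Dirichlet signatures via normalized Gammas
    sig <- matrix(stats::rgamma(m * k, shape = dirichlet_alpha, rate = 1), m, k)
    # guard against full-zero columns at very small alpha
    zero_col <- colSums(sig) == 0
    if (any(zero_col)) sig[1, zero_col] <- 1
    sig <- sweep(sig, 2, colSums(sig), "/")
    # base exposures: iid Gamma(shape 0.5, mean 1), heavy-tailed so each
    # signature is anchored by a few high-exposure samples, clipped so no
    # single program dwarfs a sample's profile; group label not consulted
    w <- pmin(matrix(stats::rgamma(k * n, shape = 0.5, rate = 0.5), k, n),
              exposure_clip)
    # jitter for the group-dominant amplification (drawn unconditionally to
    # keep the stream identical across separation values)
    jit_a <- stats::runif(sum(group_labels == "A"), 0.9, 1.1)
    jit_b <- stats::runif(sum(group_labels == "B"), 0.9, 1.1)
    list(sig = sig, w = w, jit_a = jit_a, jit_b = jit_b)
  })

  w <- out$w
  if (k >= 2L) {
    a_cols <- group_labels == "A"
    damp <- 0.2^separation
    # each group program runs at floor level outside its group ...
    w[dom["a"], ] <- w[dom["a"], ] * damp
    w[dom["b"], ] <- w[dom["b"], ] * damp
    # ... and gains separation-scaled weight in its own group
    w[dom["a"], a_cols] <- w[dom["a"], a_cols] + 1.5 * separation * out$jit_a
    w[dom["b"], !a_cols] <- w[dom["b"], !a_cols] + 1.5 * separation * out$jit_b
  }
  w <- w + 0.05 # floor: every signature minutely active in every sample

  metabolite_ids <- sprintf("met%04d", seq_len(m))
  sample_ids <- c(sprintf("A_%02d", seq_len(na)), sprintf("B_%02d", seq_len(nb)))
  dimnames(out$sig) <- list(metabolite_ids, sprintf("S%d", seq_len(k)))
  dimnames(w) <- list(sprintf("S%d", seq_len(k)), sample_ids)

  structure(
    list(true_signatures = out$sig, true_weights = w,
         group_labels = stats::setNames(group_labels, sample_ids),
         metabolite_ids = metabolite_ids, sample_ids = sample_ids,
         dominant = dom, noise_sigma = as.numeric(noise_sigma),
         separation = as.numeric(separation), seed = seed),
    class = "SyntheticGroundTruth"
  )
}

#' Render an observed abundance matrix from planted ground truth
#'
#' Computes the noiseless product of the planted factors and applies i.i.d.
#' multiplicative lognormal noise: `X[i, j] = (S W)[i, j] * exp(e)`,
#' `e ~ N(0, noise_sigma^2)`. Peak-area-like data are positive and
#' heteroscedastic, which the multiplicative model captures; at
#' `noise_sigma = 0` the output is exactly the planted product.
#'
#' @param gt a `SyntheticGroundTruth`.
#' @return a [metabolite_matrix()] with the ground truth's ids and group labels.
#' @export
render_matrix <- function(gt) {
  stopifnot(inherits(gt, "SyntheticGroundTruth"))
  clean <- gt$true_signatures %*% gt$true_weights
  x <- if (gt$noise_sigma > 0) {
    with_seed(derive_seed(gt$seed, "render"), {
      clean * exp(matrix(stats::rnorm(length(clean), 0, gt$noise_sigma),
                         nrow(clean), ncol(clean)))
    })
  } else {
    clean
  }
  metabolite_matrix(x, gt$metabolite_ids, gt$sample_ids, groups = gt$group_labels)
}

#' Generate a pathway library matched to planted signatures
#'
#' Builds `n_sets` metabolite sets over the ground truth's metabolite
#' universe. A fraction `aligned_fraction` of the sets is drawn from the
#' top-probability metabolites of one planted signature (cycling through the
#' signatures), so those sets should later be recovered as over-represented;
#' the remaining sets are uniform draws and should not.
#'
#' @param gt a `SyntheticGroundTruth`.
#' @param n_sets number of sets.
#' @param set_size members per set; at most the universe size.
#' @param aligned_fraction fraction of sets aligned with a planted signature.
#' @param seed integer seed.
#' @param top_pool size of the high-probability pool an aligned set is drawn
#'   from; defaults to `2 * set_size`.
#' @return a [pathway_library()]; aligned set names carry the signature they
#'   follow (e.g. `"aligned_S3_1"`), others are `"random_<i>"`.
#' @export
generate_pathway_library <- function(gt, n_sets = 10, set_size = 15,
                                     aligned_fraction = 0.5, seed = 1,
                                     top_pool = 2L * set_size) {
  stopifnot(inherits(gt, "SyntheticGroundTruth"))
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  aligned_fraction <- check_fraction(aligned_fraction, "aligned_fraction")
  universe <- gt$metabolite_ids
  if (set_size > length(universe)) {
    stop("invalid parameter: `set_size` exceeds the metabolite universe",
         call. = FALSE)
  }
  top_pool <- max(set_size, min(as.integer(top_pool), length(universe)))
  k <- ncol(gt$true_signatures)
  n_aligned <- round(aligned_fraction * n_sets)

  sets <- with_seed(derive_seed(seed, "pathways"), {
    out <- list()
    for (i in seq_len(n_sets)) {
      if (i <= n_aligned) {
        s <- ((i - 1L) %% k) + 1L
        pool <- universe[order(gt$true_signatures[, s], decreasing = TRUE)[seq_len(top_pool)]]
        out[[sprintf("aligned_S%d_%d", s, i)]] <- sort(sample(pool, set_size))
      } else {
        out[[sprintf("random_%d", i)]] <- sort(sample(universe, set_size))
      }
    }
    out
  })
  pathway_library(sets, universe)
}
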