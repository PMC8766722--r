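#' Specification of one synthetic imaging modality
#'
#' Describes the feature family generated for one modality of the synthetic
#' cohort: how many ROI features, how many of them carry a diagnostic signal,
#' how strong that signal is, and the correlation structure of the rest.
#'
#' Features follow a Gaussian linear factor model with unit total variance.
#' An informative feature j of subject i with group indicator g (CN = 0,
#' AD = 1) is
#'   \eqn{x_{ij} = d g_i + \lambda L_i + \sqrt{1-\lambda^2}\,\epsilon_{ij}},
#' where L is a standard-normal latent factor shared across modalities
#' (amyloid-like common pathology) and d is the standardized effect size.
#' A nuisance feature in block b is
#'   \eqn{x_{ij} = \sqrt{\rho} B_{ib} + \sqrt{1-\rho}\,\epsilon_{ij}},
#' giving within-block correlation \eqn{\rho}. Consequently, within a group,
#' two informative features of modalities with loadings \eqn{\lambda_1} and
#' \eqn{\lambda_2} have correlation \eqn{\lambda_1 \lambda_2}.
#'
#' @param name Modality label, e.g. `"smri"`, `"pet"`, `"dti"`.
#' @param n_features Total number of features (positive integer).
#' @param n_informative Number of features with a planted group-mean shift
#'   (the first `n_informative` columns); must be `<= n_features`.
#' @param effect_size Standardized group mean difference d of informative
#'   features, in units of feature standard deviation.
#' @param block_size Number of nuisance features per correlated block.
#' @param block_rho Within-block correlation of nuisance features, in [0, 1).
#' @param latent_loading Loading of informative features on the shared
#'   cross-modality latent factor, in [0, 1].
#' @return An object of class `modality_spec`.
#' @export
modality_spec <- function(name, n_features, n_informative = 0,
                          effect_size = 0, block_size = 1, block_rho = 0,
                          latent_loading = 0) {
  if (!is_count(n_features)) {
    nf_stop("n_features must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_count(n_informative, min = 0) || n_informative > n_features) {
    nf_stop("n_informative must be an integer <= n_features",
            class = "neurofuse_config_error")
  }
  if (!is_number(effect_size)) {
    nf_stop("effect_size must be a finite number", class = "neurofuse_config_error")
  }
  if (!is_count(block_size)) {
    nf_stop("block_size must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_number(block_rho) || block_rho < 0 || block_rho >= 1) {
    nf_stop("block_rho must lie in [0, 1)", class = "neurofuse_config_error")
  }
  if (!is_number(latent_loading) || latent_loading < 0 || latent_loading > 1) {
    nf_stop("latent_loading must lie in [0, 1]", class = "neurofuse_config_error")
  }
  structure(
    list(name = as.character(name)[1], n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, block_size = as.integer(block_size),
         block_rho = block_rho, latent_loading = latent_loading),
    class = "modality_spec"
  )
}

#' Configuration of a synthetic multimodal cohort
#'
#' @param n_per_group Subjects per diagnostic group (CN and AD each); >= 3.
#' @param modalities List of [modality_spec()] objects (non-empty).
#' @param seed Integer master seed; the generator is bit-reproducible for a
#'   fixed config and seed.
#' @param external_shift Additive mean shift applied to every feature of an
#'   external cohort (scanner/site offset).
#' @param external_scale Multiplicative dispersion change of an external
#'   cohort (> 0).
#' @param dropout_fraction Fraction of subjects dropped at random per modality
#'   to emulate partial multimodal coverage; 0 keeps full overlap.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group, modalities, seed = 1,
                          external_shift = 0, external_scale = 1,
                          dropout_fraction = 0) {
  if (!is_count(n_per_group, min = 3)) {
    nf_stop("n_per_group must be an integer >= 3", class = "neurofuse_config_error")
  }
  if (inherits(modalities, "modality_spec")) modalities <- list(modalities)
  if (!length(modalities) || !all(vapply(modalities, inherits, TRUE, "modality_spec"))) {
    nf_stop("modalities must be a non-empty list of modality_spec objects",
            class = "neurofuse_config_error")
  }
  nm <- vapply(modalities, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    nf_stop("modality names must be unique", class = "neurofuse_config_error")
  }
  names(modalities) <- nm
  if (!is_number(external_scale) || external_scale <= 0) {
    nf_stop("external_scale must be a positive number",
            class = "neurofuse_config_error")
  }
  if (!is_number(external_shift)) {
    nf_stop("external_shift must be a finite number", class = "neurofuse_config_error")
  }
  if (!is_number(dropout_fraction) || dropout_fraction < 0 || dropout_fraction >= 1) {
    nf_stop("dropout_fraction must lie in [0, 1)", class = "neurofuse_config_error")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), modalities = modalities,
         seed = as.integer(seed), external_shift = external_shift,
         external_scale = external_scale, dropout_fraction = dropout_fraction),
    class = "cohort_config"
  )
}

# Core sampler: one cohort realization under the factor model.
# seed_offset separates the internal/external/ensemble seed streams.
generate_cohort_impl <- function(config, seed_offset, id_prefix,
                                 shift = 0, scale = 1) {
  n <- config$n_per_group
  n_sub <- 2L * n
  g <- rep(c(0L, 1L), each = n)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_sub))

  with_seed(derive_seed(config$seed, seed_offset), {
    latent <- stats::rnorm(n_sub)
    tables <- lapply(config$modalities, function(spec) {
      p <- spec$n_features
      k <- spec$n_informative
      lam <- spec$latent_loading
      x <- matrix(0, n_sub, p)
      if (k > 0) {
        eps <- matrix(stats::rnorm(n_sub * k), n_sub, k)
        x[, seq_len(k)] <- spec$effect_size * g +
          lam * latent + sqrt(1 - lam^2) * eps
      }
      if (p > k) {
        n_nui <- p - k
        blocks <- rep(seq_len(ceiling(n_nui / spec$block_size)),
                      each = spec$block_size)[seq_len(n_nui)]
        bfac <- matrix(stats::rnorm(n_sub * max(blocks)), n_sub, max(blocks))
        eps <- matrix(stats::rnorm(n_sub * n_nui), n_sub, n_nui)
        x[, k + seq_len(n_nui)] <-
          sqrt(spec$block_rho) * bfac[, blocks, drop = FALSE] +
          sqrt(1 - spec$block_rho) * eps
      }
      x <- x * scale + shift
      dimnames(x) <- list(ids, sprintf("%s_roi%03d", spec$name, seq_len(p)))
      tab <- feature_table(x, g, spec$name)
      if (config$dropout_fraction > 0) {
        keep <- sort(sample.int(n_sub, round(n_sub * (1 - config$dropout_fraction))))
        tab <- subset_table(tab, subjects = keep)
      }
      tab
    })
    structure(
      list(
        tables = tables,
        informative = lapply(config$modalities, function(s) {
          colnames(tables[[s$name]]$x)[seq_len(s$n_informative)]
        }),
        config = config
      ),
      class = "multimodal_cohort"
    )
  })
}

#' Generate a synthetic multimodal cohort
#'
#' Draws one feature table per modality for `2 * n_per_group` subjects with
#' exactly balanced CN/AD labels. All modalities share subject identifiers,
#' labels, and the per-subject latent factor; see [modality_spec()] for the
#' generating model.
#'
#' @param config A [cohort_config()].
#' @return An object of class `multimodal_cohort`: list with `tables` (named
#'   list of [feature_table()]), `informative` (named list of the planted
#'   feature names per modality) and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(10, list(
#'   modality_spec("smri", 20, n_informative = 4, effect_size = 1.5)
#' ), seed = 7)
#' coh <- generate_multimodal_cohort(cfg)
#' coh$tables$smri
generate_multimodal_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_cohort_impl(config, seed_offset = 1L, id_prefix = "int")
}

#' Generate a distribution-shifted external cohort
#'
#' Same feature names and generating mechanism as
#' [generate_multimodal_cohort()], drawn from a different seed stream, with
#' all features shifted by `external_shift` and dispersion scaled by
#' `external_scale` — emulating an external validation cohort acquired on a
#' different scanner/protocol.
#'
#' @param config A [cohort_config()].
#' @return A `multimodal_cohort`.
#' @export
generate_external_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_cohort_impl(config, seed_offset = 2L, id_prefix = "ext",
                       shift = config$external_shift,
                       scale = config$external_scale)
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat(sprintf("<multimodal_cohort> %d modalities, seed %d\n",
              length(x$tables), x$config$seed))
  for (tab in x$tables) print(tab)
  invisible(x)
}

#' Write a cohort to disk as CSV tables plus a JSON config sidecar
#'
#' One CSV per modality (via [write_feature_table()]) and a
#' `cohort_config.json` sidecar recording the full configuration and seed so
#' the cohort can be regenerated.
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(cohort$tables), function(m) {
    p <- file.path(dir, paste0(m, ".csv"))
    write_feature_table(cohort$tables[[m]], p)
    p
  }, "")
  cfg <- cohort$config
  cfg$modalities <- lapply(cfg$modalities, unclass)
  side <- file.path(dir, "cohort_config.json")
  jsonlite::write_json(
    list(config = unclass(cfg), informative = cohort$informative),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, config = side))
}
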