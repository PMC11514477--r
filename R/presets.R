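#' Condition presets carrying the study's effect sizes
#'
#' Each preset bundles the per-condition quantities the synthetic generator
#' plants: mean replication nano-foci per Xi, Xi-pattern persistence (as a
#' distribution over 20-min live-imaging frames), the Xi EdU/PCNA
#' progression factor, the final G1 Mcm2 loading coefficient, PLA spot
#' statistics, DNA-halo radius factor and Xi Mcm2 / Mcm2-phosphoS108
#' reductions. `scramble` is the normalisation reference: all its relative
#' factors equal 1.
#'
#' Values: 138/95/140 foci per Xi; persistence 4 frames (80 min) for
#' scramble and mH2A1 KD versus a 2/3-frame mixture averaging 2.6 frames
#' (52 min) for mH2A2 KD; Xi progression factors 1.43 and 1.37; final
#' loading coefficients 4.44 / 2.77 / 4.24; PLA nuclear means 19.8 / 2 /
#' 18.2 with Xi density folds 2.5 / 1 / 2.3; halo radius factor 2.2 for
#' mH2A1 KD; Xi Mcm2 reduced 25% and Mcm2-phosphoS108 41% in mH2A1 KD.
#'
#' @param name One of `"scramble"`, `"mh2a1_kd"`, `"mh2a2_kd"`.
#' @param ... Named overrides of individual preset fields.
#' @return A `condition_preset` list.
#' @examples
#' condition_preset("scramble")
#' condition_preset("mh2a1_kd", foci_per_xi_mean = 95)
#' @export
condition_preset <- function(name = c("scramble", "mh2a1_kd", "mh2a2_kd"),
                             ...) {
  name <- match.arg(name)
  base <- switch(name,
    scramble = list(
      foci_per_xi_mean = 138,
      xi_persistence_frames = c(`4` = 1),
      edu_pcna_xi_factor = 1,
      mcm_loading_final = 4.44,
      pla_nuclear_mean = 19.8,
      pla_xi_density_fold = 2.5,
      halo_radius_factor = 1,
      mcm2_xi_reduction = 0,
      mcm2ps108_xi_reduction = 0,
      xi_onset_shift_frames = 0
    ),
    mh2a1_kd = list(
      foci_per_xi_mean = 95,
      xi_persistence_frames = c(`4` = 1),
      edu_pcna_xi_factor = 1.43,
      mcm_loading_final = 2.77,
      pla_nuclear_mean = 2,
      pla_xi_density_fold = 1,
      halo_radius_factor = 2.2,
      mcm2_xi_reduction = 0.25,
      mcm2ps108_xi_reduction = 0.41,
      xi_onset_shift_frames = -1.5
    ),
    mh2a2_kd = list(
      foci_per_xi_mean = 140,
      xi_persistence_frames = c(`2` = 0.4, `3` = 0.6),
      edu_pcna_xi_factor = 1.37,
      mcm_loading_final = 4.24,
      pla_nuclear_mean = 18.2,
      pla_xi_density_fold = 2.3,
      halo_radius_factor = 1,
      mcm2_xi_reduction = 0,
      mcm2ps108_xi_reduction = 0,
      xi_onset_shift_frames = 0
    ))
  base$name <- name
  base$noise_model <- list(type = "poisson", gain = 1)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad)) {
      stop("unknown preset fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    base[names(dots)] <- dots
  }
  validate_preset(structure(base, class = "condition_preset"))
}

validate_preset <- function(p) {
  stopifnot(inherits(p, "condition_preset"))
  counts <- c(p$foci_per_xi_mean, p$pla_nuclear_mean)
  if (any(counts < 0)) stop("preset counts must be >= 0", call. = FALSE)
  facts <- c(p$edu_pcna_xi_factor, p$mcm_loading_final,
             p$pla_xi_density_fold, p$halo_radius_factor)
  if (any(facts <= 0)) stop("preset factors must be > 0", call. = FALSE)
  fr <- c(p$mcm2_xi_reduction, p$mcm2ps108_xi_reduction)
  if (any(fr < 0 | fr > 1)) {
    stop("preset fractions must lie in [0, 1]", call. = FALSE)
  }
  d <- p$xi_persistence_frames
  if (length(d) == 0 || any(d < 0) || sum(d) <= 0) {
    stop("xi_persistence_frames must be a non-empty distribution",
         call. = FALSE)
  }
  if (is.null(names(d)) || anyNA(suppressWarnings(as.numeric(names(d))))) {
    stop("xi_persistence_frames must be named by frame counts",
         call. = FALSE)
  }
  p
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("<condition_preset>", x$name, "\n")
  cat(sprintf("  foci/Xi %g | EdU:PCNA factor %g | loading final %g\n",
              x$foci_per_xi_mean, x$edu_pcna_xi_factor, x$mcm_loading_final))
  cat(sprintf("  PLA mean %g (Xi fold %g) | halo factor %g | Mcm2 -%d%%/-%d%%\n",
              x$pla_nuclear_mean, x$pla_xi_density_fold, x$halo_radius_factor,
              round(100 * x$mcm2_xi_reduction),
              round(100 * x$mcm2ps108_xi_reduction)))
  cat("  persistence (frames):",
      paste(sprintf("%s:%g", names(x$xi_persistence_frames),
                    x$xi_persistence_frames), collapse = " "), "\n")
  invisible(x)
}

# noise application: `noise` is "none", list(type="poisson", gain=g) or
# list(type="gaussian", sd=s); intensities stay >= 0
apply_noise <- function(a, noise) {
  if (is.null(noise) || identical(noise, "none")) return(a)
  if (is.character(noise)) noise <- list(type = noise)
  d <- dim(a)
  out <- switch(noise$type,
    none = a,
    poisson = {
      gain <- noise$gain %||% 1
      stats::rpois(length(a), as.vector(a) / gain) * gain
    },
    gaussian = pmax(0, as.vector(a) + stats::rnorm(length(a),
                                                   sd = noise$sd %||% 1)),
    stop("unknown noise model: ", noise$type, call. = FALSE))
  array(out, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
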