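#' The ten-cluster trajectory taxonomy
#'
#' Five temporal response patterns in each of two directions give ten
#' clusters, labelled `a`-`j`. Letters `a`-`e` are molecules increased at
#' treatment versus baseline, `f`-`j` decreased; each letter's mirror partner
#' (a-j, b-i, c-h, d-g, e-f) is the same pattern in the opposite direction.
#' The letter assignment is a labelling convention and can be remapped
#' downstream; the pattern x direction pair is the semantic content.
#'
#' @return data.frame with columns `letter`, `pattern`, `direction`.
#' @examples
#' trajectory_classes()
#' @export
trajectory_classes <- function() {
  data.frame(
    letter = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
    pattern = c("progressive", "persistent", "overcorrection",
                "partially_reversed", "completely_reversed",
                "completely_reversed", "partially_reversed",
                "overcorrection", "persistent", "progressive"),
    direction = c(1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE)
}

# WD offset as a multiple of delta, per pattern (TRT offset is always 1)
.pattern_wd_mult <- c(progressive = 2, persistent = 1, partially_reversed = 0.5,
                      completely_reversed = 0, overcorrection = -1)

.resolve_class_label <- function(label) {
  tc <- trajectory_classes()
  if (label == "unchanged")
    return(list(pattern = "unchanged", direction = 0L))
  if (label %in% tc$letter) {
    i <- match(label, tc$letter)
    return(list(pattern = tc$pattern[i], direction = tc$direction[i]))
  }
  m <- regmatches(label, regexec("^([a-z_]+)-(up|down)$", label))[[1]]
  if (length(m) == 3) {
    pat <- switch(m[2],
                  partial = "partially_reversed",
                  complete = "completely_reversed",
                  m[2])
    if (pat %in% names(.pattern_wd_mult))
      return(list(pattern = pat, direction = if (m[3] == "up") 1L else -1L))
  }
  stop("unknown trajectory class label: ", label)
}

#' Class mean profile across the three conditions
#'
#' The noiseless per-condition mean of a molecule in a given trajectory
#' class: baseline at UnT, baseline +/- delta at treatment, and a
#' pattern-dependent level after withdrawal (2*delta progressive, delta
#' persistent, delta/2 partially reversed, 0 completely reversed, -delta
#' overcorrection, all signed by direction).
#'
#' @param label a cluster letter (`"a"`-`"j"`), `"unchanged"`, or a
#'   `"<pattern>-up"`/`"<pattern>-down"` name (pattern one of `progressive`,
#'   `persistent`, `partial`, `complete`, `overcorrection` or their full
#'   `*_reversed` forms).
#' @param baseline baseline mean, log2 units.
#' @param delta effect size, log2 units (> 0).
#' @return numeric vector `c(UnT, TRT, WD)` of condition means.
#' @examples
#' class_mean_profile("persistent-up", 20, 2)   # 20 22 22
#' class_mean_profile("e", 20, 2)               # 20 22 20
#' @export
class_mean_profile <- function(label, baseline, delta) {
  if (delta <= 0) stop("`delta` must be > 0")
  cls <- .resolve_class_label(label)
  if (cls$pattern == "unchanged") return(rep(baseline, 3))
  mult <- .pattern_wd_mult[[cls$pattern]]
  baseline + cls$direction * delta * c(0, 1, mult)
}

#' Simulation configuration
#'
#' The stated world of the generator: a three-condition design with `n = 3`
#' biological replicates per condition, additive class effects on the log2
#' scale and homoscedastic Gaussian replicate noise. Defaults place baselines
#' around 20 log2 units (typical label-free protein intensities), an effect
#' size of 2 log2 units and replicate noise of 0.25 log2 units.
#'
#' @param n_molecules number of molecules to simulate.
#' @param replicates biological replicates per condition (>= 2).
#' @param baseline_mean,baseline_spread mean and SD of per-molecule baseline
#'   abundance, log2 units.
#' @param effect_size treatment effect delta, log2 units (> 0).
#' @param noise_sd replicate noise SD sigma, log2 units (>= 0).
#' @param class_proportions named numeric vector over the 11 labels
#'   (`a`-`j`, `unchanged`) summing to 1; default uniform.
#' @param conditions length-3 character vector naming baseline, treatment
#'   and withdrawal conditions.
#' @param seed integer RNG seed.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_molecules = 1100L,
                       replicates = 3L,
                       baseline_mean = 20,
                       baseline_spread = 2,
                       effect_size = 2,
                       noise_sd = 0.25,
                       class_proportions = NULL,
                       conditions = c("UnT", "TRT", "WD"),
                       seed = 1L) {
  labels <- c(trajectory_classes()$letter, "unchanged")
  if (is.null(class_proportions))
    class_proportions <- setNames(rep(1 / 11, 11), labels)
  if (!setequal(names(class_proportions), labels))
    stop("class_proportions must be named over: ", paste(labels, collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (replicates < 2) stop("replicates must be >= 2")
  if (length(conditions) != 3 || anyDuplicated(conditions))
    stop("conditions must be 3 distinct labels")
  structure(list(n_molecules = as.integer(n_molecules),
                 replicates = as.integer(replicates),
                 baseline_mean = baseline_mean,
                 baseline_spread = baseline_spread,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 class_proportions = class_proportions,
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic perturbation-withdrawal dataset
#'
#' For each molecule: a trajectory class is drawn from
#' `class_proportions`, a baseline from
#' `Normal(baseline_mean, baseline_spread)`, and every observation is the
#' class mean ([class_mean_profile()]) plus `Normal(0, noise_sd)` replicate
#' noise. Deterministic given `config$seed` (R's default Mersenne-Twister
#' generator, seeded once per call). Draw order is fixed (classes, then
#' baselines, then one noise matrix), so two configs that differ only in the
#' labelling of `class_proportions` reuse identical draws — the basis of the
#' mirror-symmetry property.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an `ExpressionMatrix`, log2 scale) and
#'   `truth` (data.frame: `molecule_id`, `class`, `pattern`, `direction`,
#'   `delta` signed effect, `baseline`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_molecules; reps <- config$replicates
  set.seed(config$seed)
  classes <- sample(names(config$class_proportions), n, replace = TRUE,
                    prob = config$class_proportions)
  baselines <- rnorm(n, config$baseline_mean, config$baseline_spread)
  noise <- matrix(rnorm(n * 3 * reps, 0, config$noise_sd), nrow = n)

  profiles <- t(vapply(seq_len(n), function(i)
    class_mean_profile(classes[i], baselines[i], config$effect_size),
    numeric(3)))
  means <- profiles[, rep(1:3, each = reps), drop = FALSE]
  values <- means + noise
  ids <- sprintf("mol_%05d", seq_len(n))
  rownames(values) <- ids
  sample_names <- paste(rep(config$conditions, each = reps),
                        rep(seq_len(reps), 3), sep = "_")
  colnames(values) <- sample_names
  cond <- setNames(rep(config$conditions, each = reps), sample_names)

  tc <- trajectory_classes()
  idx <- match(classes, tc$letter)
  pattern <- ifelse(is.na(idx), "unchanged", tc$pattern[idx])
  direction <- ifelse(is.na(idx), 0L, tc$direction[idx])
  truth <- data.frame(molecule_id = ids,
                      class = classes,
                      pattern = pattern,
                      direction = direction,
                      delta = direction * config$effect_size,
                      baseline = baselines,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, cond, "log2"), truth = truth)
}
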