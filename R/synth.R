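## Seeded generators that emulate the statistical structure of each input
## the pipeline consumes: a two-class population alignment with a focal
## deletion whose carrier class has reduced diversity, binomial
## allele-frequency clines over latitude, and noisy embryo stripe
## landmarks. Every generator is a pure function of (parameters, seed)
## and returns the generating truth alongside the data.

synth_truth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("synth_truth: %s (seed %s)\n", x$generator, format(x$seed)))
  utils::str(x$params, no.list = TRUE)
  invisible(x)
}

#' Write a synthetic truth record as JSON
#'
#' @param truth A `synth_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synth_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# apply infinite-sites mutations (binary matrix, site positions) to an
# ancestral sequence: carriers of column s get a substitute base at pos[s]
apply_mutations <- function(ancestral, mat, pos) {
  n <- nrow(mat)
  rows <- matrix(strsplit(ancestral, "")[[1L]],
                 nrow = n, ncol = nchar(ancestral), byrow = TRUE)
  for (s in seq_len(ncol(mat))) {
    anc <- rows[1L, pos[s]]
    alt <- sample(setdiff(c("A", "C", "G", "T"), anc), 1L)
    rows[mat[, s] == 1L, pos[s]] <- alt
  }
  apply(rows, 1L, paste, collapse = "")
}

#' Synthetic two-class population alignment with a focal deletion
#'
#' Generates a gapped population alignment in which deletion carriers
#' form a reduced-diversity class. The wild-type class descends from a
#' standard neutral coalescent with per-site mutation rate `theta`; the
#' carrier class descends from an independent coalescent whose node times
#' are scaled by `diversity_reduction` (a recent-subclade surrogate), so
#' the expected carrier-class diversity is `diversity_reduction * theta`.
#' Mutations on the carrier stem (`stem_time` time units, placed outside
#' the deletion) are shared by all carriers and absent from the wild-type
#' class, putting them in perfect coupling with the deletion; carriers
#' are gapped across `del_span`.
#'
#' @param n_wt,n_del Class sizes (`>= 2` each).
#' @param theta Per-site population mutation rate.
#' @param L Alignment length in bp.
#' @param del_span Integer `c(start, length)` of the deletion (0-based
#'   start; must lie inside `[0, L)`).
#' @param diversity_reduction Factor in `(0, 1]` scaling carrier-class
#'   coalescent times (1 = no reduction; values near 0 give a nearly
#'   monomorphic carrier class).
#' @param stem_time Length of the carrier stem branch (2N-generation
#'   units) carrying class-diagnostic mutations.
#' @param seed Integer seed (mandatory).
#' @return List: `alignment` (a [alignment()] object, wild-type rows
#'   first), `span` (a [deletion_span()]), `truth` (a `synth_truth`).
#' @export
synth_population_alignment <- function(n_wt = 18L, n_del = 16L,
                                       theta = 0.005, L = 2000L,
                                       del_span = c(1000L, 72L),
                                       diversity_reduction = 0.3,
                                       stem_time = 0.5, seed) {
  n_wt <- as.integer(n_wt); n_del <- as.integer(n_del); L <- as.integer(L)
  if (n_wt < 2L || n_del < 2L) stop("need n_wt, n_del >= 2", call. = FALSE)
  if (diversity_reduction <= 0 || diversity_reduction > 1) {
    stop("diversity_reduction must be in (0, 1]", call. = FALSE)
  }
  start <- as.integer(del_span[1L]); width <- as.integer(del_span[2L])
  if (start < 0L || width < 1L || start + width > L) {
    stop("domain error: del_span outside [0, L)", call. = FALSE)
  }
  span <- deletion_span(start, start + width, "synthetic_deletion")
  out <- with_seed(seed, {
    anc <- random_sequence(L)
    theta_tot <- theta * L

    tree_wt <- simulate_tree(n_wt)
    mat_wt <- drop_mutations_theta(tree_wt, theta_tot)

    tree_del <- simulate_tree(n_del)
    tree_del$time <- tree_del$time * diversity_reduction
    mat_del <- drop_mutations_theta(tree_del, theta_tot)

    n_stem <- stats::rpois(1L, theta_tot / 2 * stem_time)

    # infinite sites: all variant positions distinct; stem mutations are
    # kept outside the deletion so they stay visible on carrier rows
    n_var <- ncol(mat_wt) + ncol(mat_del) + n_stem
    outside <- setdiff(seq_len(L), (start + 1L):(start + width))
    if (n_var > L) stop("theta too large for L (infinite sites)",
                        call. = FALSE)
    pos_stem <- sample(outside, n_stem)
    pos_rest <- sample(setdiff(seq_len(L), pos_stem),
                       ncol(mat_wt) + ncol(mat_del))
    pos_wt <- utils::head(pos_rest, ncol(mat_wt))
    pos_del <- utils::tail(pos_rest, ncol(mat_del))

    seq_wt <- apply_mutations(anc, mat_wt, pos_wt)
    stem_mat <- matrix(1L, nrow = n_del, ncol = n_stem)
    seq_del <- apply_mutations(anc, cbind(mat_del, stem_mat),
                               c(pos_del, pos_stem))
    # gap the deletion span in carriers
    gap <- strrep("-", width)
    seq_del <- paste0(substr(seq_del, 1L, start), gap,
                      substr(seq_del, start + width + 1L, L))
    ids <- c(sprintf("wt_%02d", seq_len(n_wt)),
             sprintf("del_%02d", seq_len(n_del)))
    alignment(ids, c(seq_wt, seq_del))
  })
  truth <- synth_truth("population_alignment",
                       list(n_wt = n_wt, n_del = n_del, theta = theta,
                            L = L, del_start = start, del_length = width,
                            diversity_reduction = diversity_reduction,
                            stem_time = stem_time),
                       seed)
  list(alignment = out, span = span, truth = truth)
}

#' Synthetic latitudinal allele-frequency cline
#'
#' Carrier counts `k_i ~ Binomial(n_i, b0 + b * lat_i)` for each
#' population.
#'
#' @param b0 Intercept (frequency at latitude 0).
#' @param b Slope per decimal degree.
#' @param latitudes Numeric vector of decimal latitudes.
#' @param n_per_pop Chromosomes sampled per population (recycled).
#' @param seed Integer seed (mandatory).
#' @return List: `table` (data.frame `population`, `latitude`, `n`, `k`,
#'   `frequency`), `truth`.
#' @export
synth_cline <- function(b0 = 0.35, b = -0.006,
                        latitudes = c(25.03, 28.05, 30.03, 33.03, 35.05,
                                      37.05, 39.05, 41.05, 42.0, 43.1),
                        n_per_pop = 38L, seed) {
  p <- b0 + b * latitudes
  if (any(p < 0 | p > 1)) {
    stop("domain error: b0 + b*latitude outside [0, 1]", call. = FALSE)
  }
  n <- rep_len(as.integer(n_per_pop), length(latitudes))
  k <- with_seed(seed, stats::rbinom(length(latitudes), n, p))
  tab <- data.frame(population = sprintf("pop%02d", seq_along(latitudes)),
                    latitude = latitudes, n = n, k = k,
                    frequency = k / n)
  truth <- synth_truth("cline",
                       list(b0 = b0, b = b, latitudes = latitudes,
                            n_per_pop = n), seed)
  list(table = tab, truth = truth)
}

#' Default stripe-boundary template
#'
#' Seven stripes of 4% embryo-length width with centres evenly spaced
#' from 35% to 83% egg length, the canonical layout of the seven-stripe
#' pair-rule pattern around cellularization.
#'
#' @return Named numeric vector over [boundary_names()].
#' @export
default_stripe_template <- function() {
  centers <- seq(0.35, 0.83, by = 0.08)
  tpl <- as.vector(rbind(centers - 0.02, centers + 0.02))
  names(tpl) <- boundary_names()
  tpl
}

#' Synthetic embryo stripe-boundary landmarks
#'
#' Embryos are placed on a randomly rotated and translated axis of random
#' length (image units). True boundary positions are
#' `template + class shift + orientation_effect * orientation +
#' stage_effect * (stage - 3) + line effect + Gaussian noise`; landmarks
#' are laid down at the corresponding point on the axis plus a random
#' perpendicular offset (which the projection-based recovery removes
#' exactly).
#'
#' @param n_per_class Embryos per genotype class.
#' @param template Named positions as from [default_stripe_template()].
#' @param shift List `list(boundary =, magnitude =)`: planted class
#'   effect added to one boundary of the second class ("mutant");
#'   magnitude 0 disables it.
#' @param noise_sd Landmark noise SD in relative units (default 0.01
#'   embryo lengths, visual-landmarking error).
#' @param orientation_effect Shift per unit of the 0-3 ordinal
#'   dorsal/ventral rotation score.
#' @param stage_effect Shift per developmental-stage unit (stages 1-5 in
#'   0.5 steps, centred at 3).
#' @param n_lines_per_class Inbred lines per class; embryos are split
#'   evenly.
#' @param line_sd SD of line-by-boundary random effects.
#' @param seed Integer seed (mandatory).
#' @return List: `landmarks` (data.frame consumed by
#'   [relative_positions()], with `orientation`, `stage`, `line`,
#'   `genotype`), `truth`.
#' @export
synth_embryos <- function(n_per_class = 30L,
                          template = default_stripe_template(),
                          shift = list(boundary = "S3A", magnitude = 0),
                          noise_sd = 0.01, orientation_effect = 0.004,
                          stage_effect = 0.005, n_lines_per_class = 5L,
                          line_sd = 0.005, seed) {
  bn <- boundary_names()
  stopifnot(all(bn %in% names(template)))
  if (any(template[paste0("S", 1:7, "A")] >= template[paste0("S", 1:7, "P")])) {
    stop("template must order each stripe's anterior before posterior",
         call. = FALSE)
  }
  if (!shift$boundary %in% bn) stop("unknown boundary in shift", call. = FALSE)
  n_per_class <- as.integer(n_per_class)
  n_lines <- as.integer(n_lines_per_class)
  out <- with_seed(seed, {
    classes <- c("wt", "mut")
    rows <- list()
    for (cl in classes) {
      line_ids <- sprintf("%s_line%d", cl, seq_len(n_lines))
      line_eff <- matrix(stats::rnorm(n_lines * length(bn), 0, line_sd),
                         nrow = n_lines,
                         dimnames = list(line_ids, bn))
      line_of <- rep_len(line_ids, n_per_class)
      for (e in seq_len(n_per_class)) {
        orient <- sample(0:3, 1L)
        stage <- sample(seq(1, 5, by = 0.5), 1L,
                        prob = stats::dnorm(seq(1, 5, by = 0.5), 3, 1))
        true <- template +
          orientation_effect * orient +
          stage_effect * (stage - 3) +
          line_eff[line_of[e], ] +
          stats::rnorm(length(bn), 0, noise_sd)
        if (cl == "mut" && shift$magnitude != 0) {
          true[shift$boundary] <- true[shift$boundary] + shift$magnitude
        }
        len <- stats::runif(1L, 400, 520)
        ang <- stats::runif(1L, 0, 2 * pi)
        ax <- stats::runif(1L, 0, 200); ay <- stats::runif(1L, 0, 200)
        ux <- cos(ang); uy <- sin(ang)
        perp <- stats::rnorm(length(bn), 0, 0.02 * len)
        rec <- data.frame(anterior_x = ax, anterior_y = ay,
                          posterior_x = ax + len * ux,
                          posterior_y = ay + len * uy)
        for (b in seq_along(bn)) {
          rec[[paste0(bn[b], "_x")]] <-
            ax + true[b] * len * ux - perp[b] * uy
          rec[[paste0(bn[b], "_y")]] <-
            ay + true[b] * len * uy + perp[b] * ux
        }
        rec$orientation <- orient
        rec$stage <- stage
        rec$line <- line_of[e]
        rec$genotype <- cl
        rows[[length(rows) + 1L]] <- rec
      }
    }
    do.call(rbind, rows)
  })
  truth <- synth_truth("embryos",
                       list(n_per_class = n_per_class,
                            template = as.list(template),
                            shift = shift, noise_sd = noise_sd,
                            orientation_effect = orientation_effect,
                            stage_effect = stage_effect,
                            n_lines_per_class = n_lines,
                            line_sd = line_sd), seed)
  list(landmarks = out, truth = truth)
}
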