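#' Clone lineage-output class palette
#'
#' The lineage-output classes observed for hematopoietic clones over the four
#' tracked peripheral-blood lineages: platelets (P), erythroid cells (E),
#' myeloid cells (M) and B cells (B). Labels are non-empty subsets of PEMB in
#' canonical order; multipotent PEMB clones dominate blood output in steady
#' state, so the default proportions are PEMB-heavy.
#'
#' @return Named numeric vector of class proportions summing to 1.
#' @export
default_class_proportions <- function() {
  c(PEMB = 0.35, PEM = 0.10, PEB = 0.08, PE = 0.07, MEB = 0.06, EB = 0.08,
    ME = 0.04, MB = 0.04, PM = 0.03, PB = 0.03, M = 0.05, E = 0.04, B = 0.03)
}

.LINEAGES <- c("P", "E", "M", "B")

# Internal: canonical-order lineage letters of a class label.
.label_letters <- function(label) {
  .LINEAGES[.LINEAGES %in% strsplit(label, "")[[1]]]
}

# Internal: rewrite a class label in canonical P, E, M, B letter order
# (the field also writes e.g. "MEB"/"ME"; the classifier always reports
# canonical order).
.canonical_label <- function(label) {
  vapply(label, function(l) {
    if (l %in% c("silent", "unclassified")) return(l)
    paste(.label_letters(l), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Configuration for the clonal time-course simulator
#'
#' Describes a cohort of barcoded clones tracked across weeks in the four
#' peripheral-blood lineages, optionally perturbed by an acute platelet
#' depletion. After the perturbation a fraction of multipotent (PEMB) clones
#' is repurposed (their myeloid output ceases while P, E, B persist) and a
#' fraction of previously silent clones activates, gaining myeloid or
#' platelet output.
#'
#' @param n_clones Number of clones active before any perturbation.
#' @param time_points Sampling weeks, ascending.
#' @param class_proportions Named proportions over the lineage-output classes
#'   (must sum to 1); see [default_class_proportions()].
#' @param perturbation_time Week at which the platelet depletion takes effect
#'   (must be one of `time_points`), or `NULL` for an unperturbed course.
#' @param repurpose_fraction Fraction of PEMB clones that switch off myeloid
#'   output after the perturbation.
#' @param activate_fraction Fraction of the silent clone pool that gains
#'   myeloid or platelet output after the perturbation.
#' @param n_silent Size of the silent clone pool (clones engrafted but below
#'   detection in every lineage before the perturbation).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   sampling noise applied per (clone, lineage, week) before renormalizing
#'   each (lineage, week) column to 100%.
#' @param size_range Range of the uniform per-clone base output size. The
#'   default `c(2, 10)` keeps every active clone's share of a lineage
#'   comfortably above the 0.089% detection limit at these cohort sizes;
#'   `c(1, 1)` gives equal-output clones.
#' @param seed Integer seed.
#' @return A `timecourse_config` list.
#' @export
timecourse_config <- function(n_clones = 200L,
                              time_points = c(12, 20, 28, 30),
                              class_proportions = default_class_proportions(),
                              perturbation_time = NULL,
                              repurpose_fraction = 0.7,
                              activate_fraction = 0.75,
                              n_silent = ceiling(0.2 * n_clones),
                              noise_cv = 0.2,
                              size_range = c(2, 10),
                              seed = 1L) {
  stopifnot(n_clones >= 1, length(time_points) >= 1,
            !is.unsorted(time_points), n_silent >= 0, noise_cv >= 0,
            length(size_range) == 2, size_range[1] > 0,
            size_range[1] <= size_range[2])
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  bad <- setdiff(unlist(strsplit(names(class_proportions), "")), .LINEAGES)
  if (length(bad)) {
    stop("unknown lineage letters in class names: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in c(repurpose_fraction, activate_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(perturbation_time) && !perturbation_time %in% time_points) {
    stop("perturbation_time must be one of the time_points", call. = FALSE)
  }
  structure(list(n_clones = as.integer(n_clones), time_points = time_points,
                 class_proportions = class_proportions,
                 perturbation_time = perturbation_time,
                 repurpose_fraction = repurpose_fraction,
                 activate_fraction = activate_fraction,
                 n_silent = as.integer(n_silent),
                 noise_cv = noise_cv, size_range = size_range,
                 seed = as.integer(seed)),
            class = "timecourse_config")
}

#' Simulate a clonal time course with known ground truth
#'
#' Each clone receives a lineage-output class from the configured palette and
#' a base output size; its percentage contribution to a lineage at a week is
#' its (noise-perturbed) size renormalized so that every (lineage, week)
#' column sums to 100%. Clones contribute only to the lineages of their class
#' before the perturbation. If a perturbation week is configured, repurposed
#' PEMB clones lose all myeloid output from that week on, and activated
#' silent clones gain output in myeloid or platelets.
#'
#' @param config A [timecourse_config()].
#' @param mouse Mouse identifier written into the long table.
#' @return A list with `ts`, a long tibble (`mouse`, `clone`, `lineage`,
#'   `week`, `percent`), and `truth`, a tibble of per-clone ground truth
#'   (`clone`, `class`, `status`, `activated_lineage`).
#' @examples
#' sim <- simulate_clonal_timecourse(timecourse_config(n_clones = 20, seed = 2))
#' head(sim$ts)
#' @export
simulate_clonal_timecourse <- function(config, mouse = "m1") {
  stopifnot(inherits(config, "timecourse_config"))
  set.seed(config$seed)
  n_active <- config$n_clones
  n_total <- n_active + config$n_silent
  clones <- sprintf("clone%04d", seq_len(n_total))
  classes <- c(sample(names(config$class_proportions), n_active,
                      replace = TRUE, prob = config$class_proportions),
               rep("silent", config$n_silent))
  size <- runif(n_total, config$size_range[1], config$size_range[2])
  member <- matrix(0, n_total, 4, dimnames = list(clones, .LINEAGES))
  for (i in seq_len(n_active)) {
    member[i, .label_letters(classes[i])] <- 1
  }

  pert <- config$perturbation_time
  status <- ifelse(classes == "silent", "unclassified", "stable")
  activated_lineage <- rep(NA_character_, n_total)
  repurposed <- integer(0)
  activated <- integer(0)
  if (!is.null(pert)) {
    pemb <- which(classes == "PEMB")
    repurposed <- sort(pemb[sample.int(
      length(pemb), round(config$repurpose_fraction * length(pemb)))])
    silent <- which(classes == "silent")
    activated <- sort(silent[sample.int(
      length(silent), round(config$activate_fraction * length(silent)))])
    activated_lineage[activated] <- sample(c("M", "P"), length(activated),
                                           replace = TRUE)
    status[repurposed] <- "repurposed"
    status[activated] <- "activated"
  }

  sigma <- sqrt(log(1 + config$noise_cv^2))
  rows <- vector("list", length(config$time_points))
  for (k in seq_along(config$time_points)) {
    wk <- config$time_points[k]
    raw <- member * size
    if (!is.null(pert) && wk >= pert) {
      raw[repurposed, "M"] <- 0
      if (length(activated)) {
        raw[cbind(activated, match(activated_lineage[activated], .LINEAGES))] <-
          size[activated]
      }
    }
    if (config$noise_cv > 0) {
      raw <- raw * matrix(rlnorm(n_total * 4, -sigma^2 / 2, sigma), n_total, 4)
    }
    tot <- colSums(raw)
    tot[tot == 0] <- 1  # an all-zero lineage column stays all-zero
    pct <- sweep(raw, 2, tot, "/") * 100
    rows[[k]] <- tibble(
      mouse = mouse,
      clone = rep(clones, 4),
      lineage = rep(.LINEAGES, each = n_total),
      week = wk,
      percent = as.vector(pct)
    )
  }
  ts <- do.call(rbind, rows)
  truth <- tibble(
    clone = clones,
    class = ifelse(classes == "silent", "unclassified",
                   .canonical_label(classes)),
    status = status,
    activated_lineage = activated_lineage
  )
  list(ts = as_tibble(ts), truth = truth)
}
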