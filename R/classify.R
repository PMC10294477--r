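#' Clone classification rule
#'
#' A lineage letter is credited to a clone when its percentage contribution
#' to that lineage exceeds `threshold` at `min_timepoints` time points
#' (consecutive ones when `require_consecutive`). The default threshold of
#' 0.089% is the empirical detection limit established by the calibration
#' mixtures (the smallest reliably detected clone, 1/1121 of the mix).
#' Comparisons are strict on both sides: a contribution exactly at the
#' threshold qualifies neither as present (`>`) nor as silent (`<`).
#'
#' @param threshold Percent contribution threshold (default 0.089).
#' @param min_timepoints Number of qualifying time points required
#'   (default 2).
#' @param require_consecutive Require the qualifying time points to be
#'   consecutive (default `TRUE`).
#' @return A `classification_rule` list.
#' @export
classification_rule <- function(threshold = 0.089, min_timepoints = 2L,
                                require_consecutive = TRUE) {
  stopifnot(threshold > 0, min_timepoints >= 1)
  structure(list(threshold = threshold,
                 min_timepoints = as.integer(min_timepoints),
                 require_consecutive = isTRUE(require_consecutive)),
            class = "classification_rule")
}

# Internal: longest run of TRUE values.
.max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# Internal: lineage x week percent matrix for one clone (absent entries 0).
.clone_matrix <- function(ts, clone, weeks, mouse = NULL) {
  sub <- ts[ts$clone == clone, , drop = FALSE]
  if (!is.null(mouse)) sub <- sub[sub$mouse %in% mouse, , drop = FALSE]
  sub <- sub[sub$week %in% weeks, , drop = FALSE]
  m <- matrix(0, 4, length(weeks), dimnames = list(.LINEAGES, weeks))
  if (nrow(sub)) {
    m[cbind(match(sub$lineage, .LINEAGES), match(sub$week, weeks))] <-
      sub$percent
  }
  m
}

# Internal: does a percent-by-week vector satisfy the rule?
.qualifies <- function(pct, rule) {
  above <- pct > rule$threshold
  if (rule$require_consecutive) {
    .max_run(above) >= rule$min_timepoints
  } else {
    sum(above) >= rule$min_timepoints
  }
}

#' Classify a clone's lineage output over a time window
#'
#' Builds the clone's lineage-output label ("PEMB", "PEM", "M", ...) in
#' canonical P, E, M, B order: a letter is included when the clone's
#' contribution satisfies the [classification_rule()] within the window.
#' A clone qualifying in no lineage is `"unclassified"`.
#'
#' @param ts Long clonal time series (`mouse`, `clone`, `lineage`, `week`,
#'   `percent`).
#' @param clone Clone identifier (must be present in `ts`).
#' @param rule A [classification_rule()].
#' @param window Weeks to consider (default: all weeks in `ts`).
#' @param mouse Optional mouse filter.
#' @return Label string.
#' @export
classify_clone <- function(ts, clone, rule = classification_rule(),
                           window = NULL, mouse = NULL) {
  if (!clone %in% ts$clone) {
    stop("clone '", clone, "' absent from the time series", call. = FALSE)
  }
  weeks <- sort(unique(ts$week))
  if (!is.null(window)) weeks <- weeks[weeks %in% window]
  if (length(weeks) < rule$min_timepoints) {
    stop("the window must contain at least min_timepoints time points",
         call. = FALSE)
  }
  m <- .clone_matrix(ts, clone, weeks, mouse)
  letters_in <- .LINEAGES[apply(m, 1, .qualifies, rule = rule)]
  if (!length(letters_in)) "unclassified" else paste(letters_in, collapse = "")
}

#' Classify every clone in a time series
#'
#' @inheritParams classify_clone
#' @return Tibble with `clone` and `label`.
#' @export
classify_clones <- function(ts, rule = classification_rule(), window = NULL,
                            mouse = NULL) {
  clones <- sort(unique(ts$clone))
  labels <- vapply(clones, function(cl) {
    classify_clone(ts, cl, rule, window, mouse)
  }, character(1))
  tibble(clone = clones, label = unname(labels))
}

#' Detect a repurposed multipotent clone
#'
#' A clone is repurposed when it was fully multipotent before the
#' perturbation (label "PEMB" over the pre window under the rule) and its
#' myeloid contribution stays below the threshold at every post-perturbation
#' time point, while it keeps producing platelets, erythroid and B cells.
#'
#' @inheritParams classify_clone
#' @param pre_window Weeks before the perturbation (must precede
#'   `post_window`).
#' @param post_window Weeks after the perturbation.
#' @return `TRUE`/`FALSE`.
#' @export
detect_repurposed <- function(ts, clone, rule = classification_rule(),
                              pre_window, post_window, mouse = NULL) {
  .check_windows(ts, pre_window, post_window)
  pre_label <- classify_clone(ts, clone, rule, pre_window, mouse)
  if (pre_label != "PEMB") return(FALSE)
  post_weeks <- sort(unique(ts$week[ts$week %in% post_window]))
  m_post <- .clone_matrix(ts, clone, post_weeks, mouse)["M", ]
  all(m_post < rule$threshold)
}

#' Detect a clone activated in a lineage by the perturbation
#'
#' A clone is activated in a lineage when its contribution there is below
#' the threshold (or absent) at every pre-perturbation time point and
#' exceeds the threshold at the rule's required number of post-perturbation
#' time points.
#'
#' @inheritParams detect_repurposed
#' @param lineage One of "P", "E", "M", "B".
#' @return `TRUE`/`FALSE`.
#' @export
detect_activated <- function(ts, clone, rule = classification_rule(),
                             pre_window, post_window, lineage,
                             mouse = NULL) {
  stopifnot(lineage %in% .LINEAGES)
  .check_windows(ts, pre_window, post_window)
  pre_weeks <- sort(unique(ts$week[ts$week %in% pre_window]))
  post_weeks <- sort(unique(ts$week[ts$week %in% post_window]))
  pre <- .clone_matrix(ts, clone, pre_weeks, mouse)[lineage, ]
  post <- .clone_matrix(ts, clone, post_weeks, mouse)[lineage, ]
  all(pre < rule$threshold) && .qualifies(post, rule)
}

.check_windows <- function(ts, pre_window, post_window) {
  if (!length(pre_window) || !length(post_window)) {
    stop("pre and post windows must be non-empty", call. = FALSE)
  }
  if (max(pre_window) >= min(post_window)) {
    stop("pre_window must lie strictly before post_window", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify clone dynamics across a perturbation
#'
#' Per clone: `repurposed` ([detect_repurposed()]), else `activated` (any
#' lineage per [detect_activated()]), else `lost` (classified pre but
#' unclassified post — a bookkeeping extension), else `stable` (classified
#' pre), else `unclassified`.
#'
#' @inheritParams detect_repurposed
#' @return Tibble with `clone`, `pre_label`, `post_label`, `status`,
#'   `activated_lineage`.
#' @export
classify_dynamics <- function(ts, rule = classification_rule(),
                              pre_window, post_window, mouse = NULL) {
  .check_windows(ts, pre_window, post_window)
  clones <- sort(unique(ts$clone))
  out <- lapply(clones, function(cl) {
    pre_label <- classify_clone(ts, cl, rule, pre_window, mouse)
    post_label <- classify_clone(ts, cl, rule, post_window, mouse)
    act <- .LINEAGES[vapply(.LINEAGES, function(l) {
      detect_activated(ts, cl, rule, pre_window, post_window, l, mouse)
    }, logical(1))]
    status <- if (detect_repurposed(ts, cl, rule, pre_window, post_window,
                                    mouse)) {
      "repurposed"
    } else if (length(act)) {
      "activated"
    } else if (pre_label != "unclassified" && post_label == "unclassified") {
      "lost"
    } else if (pre_label != "unclassified") {
      "stable"
    } else {
      "unclassified"
    }
    tibble(clone = cl, pre_label = pre_label, post_label = post_label,
           status = status,
           activated_lineage = if (length(act)) paste(act, collapse = "")
           else NA_character_)
  })
  do.call(rbind, out)
}

#' Cumulative lineage output per clone class
#'
#' For one time point, sums the contributions of each clone class to each
#' lineage. Clones without a classification are pooled as "unclassified";
#' per lineage the class sums add up to the lineage's total output at that
#' week.
#'
#' @inheritParams classify_clone
#' @param classifications Tibble with `clone` and `label` (e.g. from
#'   [classify_clones()]).
#' @param week Time point to summarize.
#' @return Tibble with `lineage`, `label`, `percent`.
#' @export
class_contribution_summary <- function(ts, classifications, week) {
  sub <- ts[ts$week == week, , drop = FALSE]
  if (!nrow(sub)) stop("week ", week, " absent from the time series",
                       call. = FALSE)
  lab <- classifications$label[match(sub$clone, classifications$clone)]
  lab[is.na(lab)] <- "unclassified"
  agg <- stats::aggregate(sub$percent,
                          by = list(lineage = sub$lineage, label = lab),
                          FUN = sum)
  names(agg)[3] <- "percent"
  as_tibble(agg[order(agg$lineage, -agg$percent), ])
}

#' Overlap between peripheral-blood and bone-marrow clone sets
#'
#' Presence/absence comparison of the PB dominant clone set against the
#' clones detected in each BM population and in their pooled union:
#' percentage of the combined set shared, plus the directed missed
#' fractions ([overlap_missed_fraction()]) in both directions.
#'
#' @param pb_dominant Character vector of PB dominant clone ids.
#' @param bm_detected Named list of character vectors, one per BM
#'   population.
#' @return Tibble with `population`, `shared_percent`,
#'   `missed_from_pb_percent`, `missed_from_bm_percent`.
#' @export
pb_bm_overlap <- function(pb_dominant, bm_detected) {
  stopifnot(is.list(bm_detected), !is.null(names(bm_detected)))
  pops <- c(names(bm_detected), "pooled")
  sets <- c(bm_detected, list(pooled = unique(unlist(bm_detected))))
  out <- lapply(pops, function(p) {
    bm <- sets[[p]]
    un <- union(pb_dominant, bm)
    shared <- if (length(un)) {
      100 * length(intersect(pb_dominant, bm)) / length(un)
    } else {
      NA_real_
    }
    tibble(population = p, shared_percent = shared,
           missed_from_pb_percent =
             overlap_missed_fraction(pb_dominant, bm)$missed_percent,
           missed_from_bm_percent =
             overlap_missed_fraction(bm, pb_dominant)$missed_percent)
  })
  do.call(rbind, out)
}
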