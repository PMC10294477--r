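#' Quality-control filter for single cells
#'
#' Keeps cells with more than `min_reads` total reads and a mitochondrial
#' fraction strictly below `max_mito` (the defaults reproduce the
#' 50,000-read / 10%-mitochondrial cut used for plate-based stem and
#' progenitor libraries). Every rejected cell carries its reason(s).
#'
#' @param cells Tibble with `total_reads` and `mito_fraction` columns.
#' @param min_reads Minimum total reads (strict `>`, default 50000).
#' @param max_mito Maximum mitochondrial fraction (strict `<`, default
#'   0.10).
#' @return List with `kept` (the passing cells, `qc_pass = TRUE` appended)
#'   and `rejected` (failing cells with a `reason` column).
#' @export
qc_filter_cells <- function(cells, min_reads = 50000, max_mito = 0.10) {
  stopifnot(all(c("total_reads", "mito_fraction") %in% names(cells)))
  low_reads <- !(cells$total_reads > min_reads)
  high_mito <- !(cells$mito_fraction < max_mito)
  pass <- !low_reads & !high_mito
  reason <- character(nrow(cells))
  reason[low_reads] <- "low_reads"
  reason[high_mito] <- paste0(ifelse(low_reads[high_mito], "low_reads;", ""),
                              "high_mito")
  kept <- cells[pass, , drop = FALSE]
  kept$qc_pass <- TRUE
  rejected <- cells[!pass, , drop = FALSE]
  rejected$qc_pass <- FALSE
  rejected$reason <- reason[!pass]
  list(kept = kept, rejected = rejected)
}

#' Assign a barcode to each cell from its barcode-bearing reads
#'
#' Extracts barcodes from each cell's reads ([extract_and_assign()]) and
#' counts reads per (cell, barcode). The top barcode is assigned when its
#' count reaches `min_count`; if a second barcode also reaches `min_count`
#' the cell is flagged as multi-barcode (possible doublet) and left
#' unassigned — by the collision probability `(1/library size)^count`,
#' several concordant reads for two different barcodes in one well are far
#' too unlikely to be chance.
#'
#' @param cell_reads Tibble with `cell_id` and `sequence` columns.
#' @param library A [generate_barcode_library()] result.
#' @param fwd_anchor An [anchor_spec()]; per-cell amplicons have no
#'   multiplex tag, so the anchor is expected at position 1.
#' @param min_count Minimum reads supporting an assignment (default 3).
#' @param policy Assignment policy, as in [extract_and_assign()].
#' @return Tibble with `cell_id`, `barcode_id` (`NA` when unassigned),
#'   `barcode_read_count`, `multi_barcode`.
#' @export
assign_cell_barcodes <- function(cell_reads, library,
                                 fwd_anchor = anchor_spec(
                                   fwd_anchor_sequence(),
                                   expected_start = 1, window = 1),
                                 min_count = 3L,
                                 policy = c("exact", "correct1")) {
  policy <- match.arg(policy)
  stopifnot(all(c("cell_id", "sequence") %in% names(cell_reads)))
  bc <- extract_and_assign(cell_reads$sequence, fwd_anchor, library, policy)
  cells <- unique(cell_reads$cell_id)
  out <- lapply(cells, function(cl) {
    b <- bc[cell_reads$cell_id == cl]
    b <- b[!is.na(b)]
    if (!length(b)) {
      return(tibble(cell_id = cl, barcode_id = NA_character_,
                    barcode_read_count = 0L, multi_barcode = FALSE))
    }
    tab <- sort(table(b), decreasing = TRUE)
    top <- as.integer(tab[1])
    second <- if (length(tab) > 1) as.integer(tab[2]) else 0L
    multi <- top >= min_count && second >= min_count
    assigned <- top >= min_count && !multi
    tibble(cell_id = cl,
           barcode_id = if (assigned) names(tab)[1] else NA_character_,
           barcode_read_count = if (assigned) top else 0L,
           multi_barcode = multi)
  })
  do.call(rbind, out)
}

#' Annotate cells with their clone's blood lineage-output class
#'
#' Copies the peripheral-blood classification label onto every QC-passing,
#' barcode-assigned cell of the same mouse. Cells whose barcode has no PB
#' classification are labeled `"BM-only"` (clones producing progenitors but
#' no detected mature blood output); unassigned or QC-failing cells get
#' `NA`.
#'
#' @param cells Tibble with `barcode_id` and optionally `qc_pass` and
#'   `mouse` columns.
#' @param classifications Tibble with `clone`, `label` and optionally
#'   `mouse`.
#' @return `cells` with a `clone_label` column appended.
#' @export
annotate_cells_with_clone_class <- function(cells, classifications) {
  stopifnot("barcode_id" %in% names(cells),
            all(c("clone", "label") %in% names(classifications)))
  if ("mouse" %in% names(cells) && "mouse" %in% names(classifications)) {
    extra <- setdiff(unique(cells$mouse), unique(classifications$mouse))
    if (length(extra)) {
      stop("cells from mouse/mice ", paste(extra, collapse = ", "),
           " have no classification table", call. = FALSE)
    }
  }
  eligible <- !is.na(cells$barcode_id)
  if ("qc_pass" %in% names(cells)) eligible <- eligible & cells$qc_pass
  lab <- classifications$label[match(cells$barcode_id,
                                     classifications$clone)]
  clone_label <- rep(NA_character_, nrow(cells))
  clone_label[eligible] <- ifelse(is.na(lab[eligible]), "BM-only",
                                  lab[eligible])
  cells$clone_label <- clone_label
  cells
}

#' Distribution of a clone's cells across bone-marrow populations
#'
#' Percentage of the clone's cells found in each profiled population,
#' scaled to sum to 100.
#'
#' @param cells Tibble with `population` and `barcode_id` columns.
#' @param clone Barcode id of the clone.
#' @return Named numeric vector of percentages over the populations present
#'   in `cells`.
#' @export
clone_population_distribution <- function(cells, clone) {
  pops <- unique(cells$population)
  sub <- cells[!is.na(cells$barcode_id) & cells$barcode_id == clone, ,
               drop = FALSE]
  if (!nrow(sub)) {
    stop("no cells carry clone '", clone, "'", call. = FALSE)
  }
  tab <- table(factor(sub$population, levels = pops))
  setNames(100 * as.vector(tab) / nrow(sub), pops)
}

#' Pseudo-bulk aggregation of single-cell gene counts
#'
#' Sums the gene count columns of all member cells of each group (for
#' example clone-status by mouse), producing replicate units suitable for
#' bulk differential-expression tools. Aggregation conserves mass: each
#' group column equals the elementwise sum of its member cells.
#'
#' @param expression Genes x cells count matrix with cell ids as column
#'   names.
#' @param groups Named character vector mapping cell ids to group ids;
#'   every named cell must be present in `expression`.
#' @param min_cells Groups with fewer member cells are flagged (default 2).
#' @return A `pseudo_bulk` list: `counts` (genes x groups), `members`
#'   (cells per group), `small_groups`.
#' @export
pseudobulk_aggregate <- function(expression, groups, min_cells = 2L) {
  stopifnot(!is.null(names(groups)), !is.null(colnames(expression)))
  missing <- setdiff(names(groups), colnames(expression))
  if (length(missing)) {
    stop("cells absent from the expression matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(groups))) {
    stop("each cell may belong to at most one group", call. = FALSE)
  }
  m <- expression[, names(groups), drop = FALSE]
  agg <- t(rowsum(t(m), group = unname(groups)))
  members <- split(names(groups), unname(groups))
  small <- names(members)[lengths(members) < min_cells]
  structure(list(counts = agg, members = members, small_groups = small),
            class = "pseudo_bulk")
}
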