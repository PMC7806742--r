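#' Default mark-to-region mapping
#'
#' JMJD2B and H3K9me3 are read at promoters, H3K36me3 at gene bodies — the
#' compartments in which each is evaluated against expression.
#' @export
DEFAULT_MARK_REGIONS <- c(JMJD2B = "promoter", H3K9me3 = "promoter",
                          H3K36me3 = "gene_body")

# Short state-code labels per mark, used by classify_state().
DEFAULT_MARK_LABELS <- c(JMJD2B = "J", H3K9me3 = "K9", H3K36me3 = "K36")

#' Build the gene x mark x timepoint presence table
#'
#' A mark is present on a gene at a timepoint iff the gene's assigned region
#' (promoter or gene body, per `mark_regions`) overlaps at least one peak of
#' that mark at that timepoint. Every declared mark/timepoint needs a peak
#' set (possibly empty).
#'
#' @param genes `GRanges` gene models with `gene_id`
#' @param promoters,bodies `GRanges` windows carrying `gene_id`, aligned
#'   with `genes`
#' @param peaks nested list: `peaks[[mark]][[timepoint]]` is a `GRanges`
#' @param mark_regions named character vector mapping mark to
#'   `"promoter"`/`"gene_body"` (default [DEFAULT_MARK_REGIONS])
#' @param timepoints timepoint vocabulary (default [TIMEPOINTS])
#' @return object of class `mark_status`: list of per-mark logical matrices
#'   (genes x timepoints) plus `gene_id`, `mark_regions`, `timepoints`
#' @export
build_mark_status <- function(genes, promoters, bodies, peaks,
                              mark_regions = DEFAULT_MARK_REGIONS,
                              timepoints = TIMEPOINTS) {
  gene_id <- mcols(genes)$gene_id
  if (!identical(mcols(promoters)$gene_id, gene_id) ||
      !identical(mcols(bodies)$gene_id, gene_id))
    stop_fmt("promoters/bodies must align with genes by gene_id")
  status <- list()
  for (mark in names(mark_regions)) {
    if (is.null(peaks[[mark]]))
      stop_fmt("no peak sets declared for mark '%s'", mark)
    region <- if (mark_regions[[mark]] == "promoter") promoters else bodies
    m <- matrix(FALSE, length(genes), length(timepoints),
                dimnames = list(gene_id, timepoints))
    for (tp in timepoints) {
      ps <- peaks[[mark]][[tp]]
      if (is.null(ps))
        stop_fmt("no peak set for mark '%s' at timepoint '%s'", mark, tp)
      m[, tp] <- overlap_any(region, ps)$hit
    }
    status[[mark]] <- m
  }
  structure(list(status = status, gene_id = gene_id,
                 mark_regions = mark_regions, timepoints = timepoints),
            class = "mark_status")
}

#' @export
print.mark_status <- function(x, ...) {
  cat(sprintf("Mark status: %d genes, marks %s, timepoints %s\n",
              length(x$gene_id),
              paste(names(x$status), collapse = "/"),
              paste(x$timepoints, collapse = "/")))
  invisible(x)
}

#' Combinatorial occupancy state per gene
#'
#' Concatenates presence/absence of each configured mark into a state code
#' such as `"J+K9+K36-"` (promoter JMJD2B and H3K9me3 present, gene-body
#' H3K36me3 absent). With three marks the assignment is an exhaustive,
#' exclusive partition into the 8 possible codes.
#'
#' @param status a `mark_status`
#' @param timepoint one timepoint
#' @param labels named short labels per mark (default [DEFAULT_MARK_LABELS]
#'   where applicable, else the mark name)
#' @return character vector of state codes, one per gene (named by gene)
#' @export
classify_state <- function(status, timepoint, labels = NULL) {
  stopifnot(inherits(status, "mark_status"))
  if (!timepoint %in% status$timepoints) stop_fmt("unknown timepoint '%s'", timepoint)
  marks <- names(status$status)
  if (is.null(labels)) {
    labels <- ifelse(marks %in% names(DEFAULT_MARK_LABELS),
                     DEFAULT_MARK_LABELS[marks], marks)
    names(labels) <- marks
  }
  parts <- vapply(marks, function(mk) {
    ifelse(status$status[[mk]][, timepoint], paste0(labels[[mk]], "+"),
           paste0(labels[[mk]], "-"))
  }, character(length(status$gene_id)))
  codes <- apply(matrix(parts, ncol = length(marks)), 1, paste0, collapse = "")
  setNames(codes, status$gene_id)
}

#' Presence trajectory and gain/loss dynamics of one mark
#'
#' The trajectory is a presence string over the timepoints (`"P"` present,
#' `"A"` absent, e.g. `"PPA"`). Each consecutive-timepoint phase is labelled
#' `gain` (absence to presence), `loss` (presence to absence),
#' `persistent_present` or `persistent_absent`.
#'
#' @param status a `mark_status`
#' @param mark one configured mark
#' @return data.frame with `gene_id`, `trajectory`, and one `phase_*`
#'   column per consecutive timepoint pair
#' @export
classify_dynamics <- function(status, mark) {
  stopifnot(inherits(status, "mark_status"))
  m <- status$status[[mark]]
  if (is.null(m)) stop_fmt("unknown mark '%s'", mark)
  tp <- status$timepoints
  if (length(tp) < 2L) stop_fmt("dynamics needs >= 2 timepoints")
  traj <- apply(ifelse(m, "P", "A"), 1, paste0, collapse = "")
  out <- data.frame(gene_id = status$gene_id, trajectory = unname(traj),
                    stringsAsFactors = FALSE)
  for (i in seq_len(length(tp) - 1L)) {
    lab <- phase_label(m[, i], m[, i + 1L])
    out[[paste0("phase_", tp[i], "_", tp[i + 1L])]] <- lab
  }
  out
}

# gain <=> absent -> present; loss <=> present -> absent.
phase_label <- function(before, after) {
  ifelse(!before & after, "gain",
         ifelse(before & !after, "loss",
                ifelse(before, "persistent_present", "persistent_absent")))
}

#' Cross-tabulate DEG direction against mark dynamics
#'
#' Counts DEG direction (`up`/`down`) against the mark's phase label for the
#' same differentiation phase. A gene is negatively correlated with the mark
#' when it is upregulated with mark loss or downregulated with mark gain.
#' Optionally, for a second mark, the subset of negative-correlation genes
#' whose second-mark phase label is the reverse (gain vs loss) of the first
#' mark's label is reported — the "reverse pattern" set.
#'
#' @param degs data.frame from [call_degs()] for one timepoint pair
#' @param dynamics data.frame from [classify_dynamics()] for the first mark
#' @param phase name of the phase column in `dynamics` (e.g.
#'   `"phase_D0_D2"`)
#' @param dynamics2 optional second-mark dynamics for the reverse-pattern set
#' @return list with `counts` (direction x phase-label table over up/down
#'   DEGs), `negative_genes`, `n_deg`, and (if `dynamics2` given)
#'   `reverse_genes`
#' @export
deg_dynamics_crosstab <- function(degs, dynamics, phase, dynamics2 = NULL) {
  if (!phase %in% names(dynamics)) stop_fmt("phase column '%s' not in dynamics", phase)
  missing_g <- setdiff(degs$gene_id, dynamics$gene_id)
  if (length(missing_g))
    stop_fmt("%d DEG gene(s) missing from dynamics (first: %s)",
             length(missing_g), missing_g[1])
  lab <- dynamics[[phase]][match(degs$gene_id, dynamics$gene_id)]
  sel <- degs$direction %in% c("up", "down")
  counts <- table(direction = factor(degs$direction[sel], c("up", "down")),
                  dynamics = factor(lab[sel], c("gain", "loss",
                                                "persistent_present",
                                                "persistent_absent")))
  neg <- (degs$direction == "up" & lab == "loss") |
         (degs$direction == "down" & lab == "gain")
  out <- list(counts = counts,
              negative_genes = degs$gene_id[neg],
              n_deg = sum(sel))
  if (!is.null(dynamics2)) {
    lab2 <- dynamics2[[phase]][match(degs$gene_id, dynamics2$gene_id)]
    rev_pat <- neg & ((lab == "loss" & lab2 == "gain") |
                      (lab == "gain" & lab2 == "loss"))
    out$reverse_genes <- degs$gene_id[rev_pat]
  }
  out
}

#' Complex-category vocabulary
#' @export
COMPLEX_CATEGORIES <- c("JMJD2B-TFAP2C-LSD1", "TFAP2C-LSD1", "JMJD2B-TFAP2C",
                        "JMJD2B-LSD1", "JMJD2B_only", "TFAP2C_only",
                        "LSD1_only", "unbound")

#' Assign co-factor complex categories to loci
#'
#' Each locus (typically a promoter window) takes exactly one category from
#' the triple of >= 1 bp overlap indicators against the JMJD2B, TFAP2C and
#' LSD1 peak sets; the tallies partition the input.
#'
#' @param loci `GRanges`
#' @param jmjd2b,tfap2c,lsd1 `GRanges` peak sets
#' @return list with `category` (per-locus factor over
#'   [COMPLEX_CATEGORIES]) and `tally`
#' @export
assign_complex <- function(loci, jmjd2b, tfap2c, lsd1) {
  j <- overlap_any(loci, jmjd2b)$hit
  t <- overlap_any(loci, tfap2c)$hit
  l <- overlap_any(loci, lsd1)$hit
  cat <- character(length(loci))
  cat[j & t & l] <- "JMJD2B-TFAP2C-LSD1"
  cat[!j & t & l] <- "TFAP2C-LSD1"
  cat[j & t & !l] <- "JMJD2B-TFAP2C"
  cat[j & !t & l] <- "JMJD2B-LSD1"
  cat[j & !t & !l] <- "JMJD2B_only"
  cat[!j & t & !l] <- "TFAP2C_only"
  cat[!j & !t & l] <- "LSD1_only"
  cat[!j & !t & !l] <- "unbound"
  cat <- factor(cat, levels = COMPLEX_CATEGORIES)
  list(category = cat, tally = table(cat))
}

#' Percentage with its exact ratio
#'
#' Reporting convention: percentage rounded to the nearest integer, half
#' away from zero, alongside the exact ratio.
#'
#' @param numerator,denominator non-negative counts, numerator <=
#'   denominator, denominator > 0
#' @return list with `percent` (integer), `ratio`, `label` ("num/den")
#' @export
summarize_fractions <- function(numerator, denominator) {
  if (denominator <= 0) stop_fmt("denominator must be > 0")
  if (numerator > denominator) stop_fmt("numerator exceeds denominator")
  list(percent = as.integer(round_half_up(100 * numerator / denominator)),
       ratio = numerator / denominator,
       label = sprintf("%d/%d", as.integer(numerator), as.integer(denominator)))
}
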