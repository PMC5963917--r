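# PSI/PIR estimation and Bayesian comparison of alternative-splicing
# events, with the standard event filters and site-to-event association.
#
# The isoform-aware sampler of MISO-class tools is replaced by a
# closed-form beta-binomial model on inclusion/exclusion junction counts:
# under H1 the two conditions have independent inclusion fractions
# psi_a, psi_b ~ Beta(1,1); under H0 they share one psi ~ Beta(1,1).  The
# Bayes factor is a ratio of Beta functions.

#' Point estimate of percent spliced in (or percent intron retained)
#'
#' Posterior mean under a uniform prior, `(inc + 1) / (inc + exc + 2)`,
#' plus the raw ratio.  Both are `NA` (flagged, not an error) when
#' `inc + exc == 0`.
#'
#' @param inclusion,exclusion non-negative junction read counts
#'   (vectorised).
#' @return data.frame with columns `psi` (posterior mean), `psi_raw` and
#'   `defined`.
#' @export
psi_point <- function(inclusion, exclusion) {
  stopifnot(all(inclusion >= 0), all(exclusion >= 0))
  tot <- inclusion + exclusion
  data.frame(
    psi = ifelse(tot > 0, (inclusion + 1) / (tot + 2), NA_real_),
    psi_raw = ifelse(tot > 0, inclusion / tot, NA_real_),
    defined = tot > 0)
}

#' Bayesian comparison of inclusion fractions between two conditions
#'
#' Closed-form Bayes factor for "psi differs" vs "psi shared" under
#' independent Beta(1,1) priors:
#' `BF10 = B(a_inc+1, a_exc+1) * B(b_inc+1, b_exc+1) /
#'         B(a_inc+b_inc+1, a_exc+b_exc+1)`.
#' `delta_psi` is the difference of posterior-mean PSIs (condition a minus
#' condition b).
#'
#' @param a_inc,a_exc,b_inc,b_exc non-negative counts; each condition must
#'   have a positive total.
#' @return list with `delta_psi`, `bayes_factor`, `psi_a`, `psi_b`.
#' @export
delta_psi_bayes <- function(a_inc, a_exc, b_inc, b_exc) {
  if (a_inc + a_exc <= 0 || b_inc + b_exc <= 0)
    stop("untestable: zero total reads in a condition")
  lbf <- lbeta(a_inc + 1, a_exc + 1) + lbeta(b_inc + 1, b_exc + 1) -
    lbeta(a_inc + b_inc + 1, a_exc + b_exc + 1)
  psi_a <- (a_inc + 1) / (a_inc + a_exc + 2)
  psi_b <- (b_inc + 1) / (b_inc + b_exc + 2)
  list(delta_psi = psi_a - psi_b, bayes_factor = exp(lbf),
       psi_a = psi_a, psi_b = psi_b)
}

#' Default splicing-event significance thresholds
#'
#' The standard filter set: at least one inclusion and one exclusion read
#' in each sample, at least 10 reads of any kind in one of the samples,
#' minimum |delta PSI| of 0.2 and Bayes factor at least 5.  All bounds are
#' inclusive.
#'
#' @return named list of thresholds.
#' @export
event_filter_defaults <- function() {
  list(min_inc = 1L, min_exc = 1L, min_sum = 10L,
       min_delta_psi = 0.2, min_bayes_factor = 5)
}

#' Apply the event significance filters
#'
#' @param a_inc,a_exc,b_inc,b_exc per-condition counts.
#' @param delta_psi,bayes_factor computed comparison results (see
#'   [delta_psi_bayes()]).
#' @param thresholds list as returned by [event_filter_defaults()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed clause names among `num-inc`, `num-exc`, `num-sum-inc-exc`,
#'   `delta-psi`, `bayes-factor`).
#' @export
apply_event_filters <- function(a_inc, a_exc, b_inc, b_exc,
                                delta_psi, bayes_factor,
                                thresholds = event_filter_defaults()) {
  th <- utils::modifyList(event_filter_defaults(), thresholds)
  reasons <- character(0)
  if (a_inc < th$min_inc || b_inc < th$min_inc)
    reasons <- c(reasons, "num-inc")
  if (a_exc < th$min_exc || b_exc < th$min_exc)
    reasons <- c(reasons, "num-exc")
  if (max(a_inc + a_exc, b_inc + b_exc) < th$min_sum)
    reasons <- c(reasons, "num-sum-inc-exc")
  if (abs(delta_psi) < th$min_delta_psi)
    reasons <- c(reasons, "delta-psi")
  if (bayes_factor < th$min_bayes_factor)
    reasons <- c(reasons, "bayes-factor")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Compare splicing events between two conditions and filter
#'
#' Replicate columns within a condition are summed before comparison.
#'
#' @param events data.frame with columns `event_id`, `type`, `gene_id`,
#'   `chrom`, `strand`, `coord_start`, `coord_end` plus per-sample count
#'   columns `inc_<sample>` and `exc_<sample>`.
#' @param samples_a,samples_b character vectors of sample names for the
#'   two conditions.
#' @param thresholds see [event_filter_defaults()].
#' @return the events data.frame augmented with `psi_a`, `psi_b`
#'   (posterior means; `pir_*` semantics for IR events), `delta_psi`,
#'   `bayes_factor`, `pass`, `reasons`, `untestable`.
#' @export
compare_events <- function(events, samples_a, samples_b,
                           thresholds = event_filter_defaults()) {
  sum_cols <- function(prefix, samples) {
    cols <- paste0(prefix, samples)
    miss <- setdiff(cols, names(events))
    if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
    if (length(cols) == 1L) events[[cols]] else rowSums(events[cols])
  }
  a_inc <- sum_cols("inc_", samples_a); a_exc <- sum_cols("exc_", samples_a)
  b_inc <- sum_cols("inc_", samples_b); b_exc <- sum_cols("exc_", samples_b)
  n <- nrow(events)
  events$psi_a <- events$psi_b <- events$delta_psi <-
    events$bayes_factor <- NA_real_
  events$pass <- FALSE
  events$reasons <- NA_character_
  events$untestable <- (a_inc + a_exc == 0) | (b_inc + b_exc == 0)
  for (i in seq_len(n)) {
    if (events$untestable[i]) { events$reasons[i] <- "untestable"; next }
    cmp <- delta_psi_bayes(a_inc[i], a_exc[i], b_inc[i], b_exc[i])
    flt <- apply_event_filters(a_inc[i], a_exc[i], b_inc[i], b_exc[i],
                               cmp$delta_psi, cmp$bayes_factor, thresholds)
    events$psi_a[i] <- cmp$psi_a
    events$psi_b[i] <- cmp$psi_b
    events$delta_psi[i] <- cmp$delta_psi
    events$bayes_factor[i] <- cmp$bayes_factor
    events$pass[i] <- flt$pass
    events$reasons[i] <- if (flt$pass) "" else paste(flt$reasons, collapse = ";")
  }
  events
}

#' Associate binding sites with splicing events
#'
#' Tallies significant events per type and direction of change, computes
#' the fraction of significant events whose host gene's co-transcribed
#' region contains at least one site, and, for skipped-exon (SE) events,
#' expresses nearby site positions in splice-site-relative coordinates:
#' negative distances upstream of the 3' splice site, a length-normalised
#' position in \\[0, 1\\] inside the exon, and positive distances downstream
#' of the 5' splice site (all in transcript orientation).
#'
#' @param events output of [compare_events()] (needs `pass`, `delta_psi`,
#'   `type`, `gene_id`, `coord_start`, `coord_end`, `chrom`, `strand`).
#' @param sites a [binding_site_set()].
#' @param annotation a [genome_annotation()].
#' @param metagene_halfwidth how far (nt) outside the SE exon to collect
#'   sites for the metagene map.
#' @return list with `type_tally` (data.frame: type, n_total, n_pass,
#'   n_up, n_down), `bound_fraction` (+ `n_bound`, `n_significant`) and
#'   `se_metagene` (data.frame: event_id, pos, region, rel_coord).
#' @export
event_binding_association <- function(events, sites, annotation,
                                      metagene_halfwidth = 200L) {
  types <- sort(unique(events$type))
  tt <- do.call(rbind, lapply(types, function(ty) {
    ev <- events[events$type == ty, ]
    data.frame(type = ty, n_total = nrow(ev), n_pass = sum(ev$pass),
               n_up = sum(ev$pass & ev$delta_psi > 0),
               n_down = sum(ev$pass & ev$delta_psi < 0),
               stringsAsFactors = FALSE)
  }))
  sig <- events[events$pass, , drop = FALSE]
  regions <- cotranscribed_regions(annotation)
  key_r <- paste(regions$chrom, regions$strand)
  key_s <- paste(sites$chrom, sites$strand)
  gene_bound <- vapply(unique(regions$gene_id), function(gid) {
    rg <- regions[regions$gene_id == gid, , drop = FALSE]
    any(vapply(seq_len(nrow(rg)), function(i) {
      any(key_s == paste(rg$chrom[i], rg$strand[i]) &
            sites$pos >= rg$start[i] & sites$pos < rg$end[i])
    }, logical(1)))
  }, logical(1))
  known <- sig$gene_id %in% names(gene_bound)
  if (any(!known))
    warning(sprintf("%d significant event(s) with no host gene skipped",
                    sum(!known)))
  sig <- sig[known, , drop = FALSE]
  n_bound <- sum(gene_bound[sig$gene_id])
  bound_fraction <- if (nrow(sig) > 0L) n_bound / nrow(sig) else NA_real_
  # SE metagene: site positions relative to the cassette exon
  se <- events[events$type == "SE", , drop = FALSE]
  meta <- list()
  for (i in seq_len(nrow(se))) {
    es <- se$coord_start[i]; ee <- se$coord_end[i]
    st <- se$strand[i]
    cand <- sites[key_s == paste(se$chrom[i], st) &
                    sites$pos >= es - metagene_halfwidth &
                    sites$pos < ee + metagene_halfwidth, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # transcript-orientation offset from each splice site
    for (j in seq_len(nrow(cand))) {
      p <- cand$pos[j]
      inside <- p >= es && p < ee
      if (inside) {
        frac <- if (st == "+") (p - es) / (ee - es) else
          (ee - 1L - p) / (ee - es)
        meta[[length(meta) + 1L]] <- data.frame(
          event_id = se$event_id[i], pos = p, region = "exon",
          rel_coord = frac, stringsAsFactors = FALSE)
      } else {
        # upstream of 3'SS is negative; downstream of 5'SS positive
        if (st == "+") {
          rel <- if (p < es) p - es else p - (ee - 1L)
        } else {
          rel <- if (p >= ee) (ee - 1L) - p else es - p
        }
        meta[[length(meta) + 1L]] <- data.frame(
          event_id = se$event_id[i], pos = p,
          region = if (rel < 0) "upstream" else "downstream",
          rel_coord = rel, stringsAsFactors = FALSE)
      }
    }
  }
  se_meta <- if (length(meta) > 0L) do.call(rbind, meta) else
    data.frame(event_id = character(0), pos = integer(0),
               region = character(0), rel_coord = numeric(0))
  list(type_tally = tt, bound_fraction = bound_fraction,
       n_bound = n_bound, n_significant = nrow(sig), se_metagene = se_meta)
}
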