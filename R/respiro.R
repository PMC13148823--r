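## Flux extraction from SUIT traces: steady-state window segmentation,
## OLS slope -> JO2 conversion, technical-replicate pooling, coupling.

.substrateSuffix <- c(PM = "PM", D = "D", G = "G", S = "S", PC = "PC",
                      M = "M", CC = "C")

#' Segment a trace into composite-state analysis windows
#'
#' Splits the trace at its injection events. Each inter-event interval
#' contributes one analysis window that starts `discard_s` seconds after
#' the injection (mixing/stabilization) and spans at most `window_s`
#' seconds, truncated at the next event. Composite state labels accumulate
#' substrate additions (`E -> PM -> PMD -> PMDG -> PMDGS`, cytochrome c
#' appends `C`); an inhibitor restarts the label (`OMY`; `AMA`; antimycin A
#' followed by rotenone gives `AMA_ROT`). The pre-first-event segment is
#' the endogenous state `E`.
#'
#' @param trace a [RespirometryTrace-class].
#' @param discard_s seconds discarded after each injection (default 30).
#' @param window_s maximum analysis-window length in seconds (default 60).
#'
#' @return data.frame with one row per state: `state`, `t_start`, `t_end`
#'   (window bounds, s), `i_start`, `i_end` (point indices), and `missing`
#'   (TRUE when `discard_s` consumed the whole interval; such states are
#'   flagged, never silently dropped).
#' @export
segmentStates <- function(trace, discard_s = 30, window_s = 60) {
  stopifnot(discard_s >= 0, window_s > 0)
  ev <- trace@events
  tt <- trace@time
  bounds <- c(tt[1L], ev$time_s, tt[length(tt)] + .Machine$double.eps)
  # composite label per segment
  labels <- character(nrow(ev) + 1L)
  labels[1L] <- "E"
  cur <- ""
  for (k in seq_len(nrow(ev))) {
    lab <- ev$label[k]
    if (lab %in% .inhibitorLabels()) {
      labels[k + 1L] <- if (lab == "ROT" && labels[k] == "AMA")
        "AMA_ROT" else lab
    } else {
      base <- if (labels[k] == "E") "" else labels[k]
      labels[k + 1L] <- paste0(base, .substrateSuffix[[lab]])
    }
  }
  out <- lapply(seq_along(labels), function(k) {
    seg_start <- bounds[k]
    seg_end <- bounds[k + 1L]
    w0 <- seg_start + discard_s
    w1 <- min(w0 + window_s, seg_end)
    if (w1 <= w0) {
      return(data.frame(state = labels[k], t_start = NA_real_,
                        t_end = NA_real_, i_start = NA_integer_,
                        i_end = NA_integer_, missing = TRUE))
    }
    idx <- which(tt >= w0 & tt <= w1)
    if (length(idx) < 3L) {
      return(data.frame(state = labels[k], t_start = w0, t_end = w1,
                        i_start = NA_integer_, i_end = NA_integer_,
                        missing = TRUE))
    }
    data.frame(state = labels[k], t_start = w0, t_end = w1,
               i_start = idx[1L], i_end = idx[length(idx)], missing = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate oxygen flux over a window
#'
#' Ordinary least-squares slope of O2 concentration versus time over the
#' index range, converted to a specific flux:
#' `JO2 = -slope (uM/s) * chamber_volume_ml * 1000 / amount`, i.e.
#' pmol O2 s-1 per mg wet weight (or per million cells). Consumption is
#' positive. Negative fitted fluxes are retained, not clamped.
#'
#' @param trace a [RespirometryTrace-class].
#' @param indexRange integer vector `c(first, last)` of point indices.
#' @return numeric flux (pmol s-1 per amount unit).
#' @examples
#' tr <- RespirometryTrace("s1", "benign", 1, time = 0:60,
#'   o2 = 180 - 0.01 * (0:60),
#'   events = data.frame(time_s = numeric(), label = character()),
#'   chamberVolumeMl = 2, amount = 4)
#' estimateJO2(tr, c(1, 61))  # 0.01 * 2 * 1000 / 4 = 5
#' @export
estimateJO2 <- function(trace, indexRange) {
  idx <- seq.int(indexRange[1L], indexRange[2L])
  if (length(idx) < 3L)
    stop("at least 3 points are required to fit a flux")
  fit <- stats::lm.fit(cbind(1, trace@time[idx]), trace@o2[idx])
  slope <- fit$coefficients[2L]
  unname(-slope * trace@chamberVolumeMl * 1000 / trace@amount)
}

#' Build a per-state flux table from a trace cohort
#'
#' Segments every trace, fits each non-missing state window, and pools
#' technical replicates of the same biological sample by arithmetic mean.
#' The replicate-level fits are retained for audit in the `"replicates"`
#' attribute.
#'
#' @param traces list of [RespirometryTrace-class] objects (technical
#'   replicates share a `sampleId`). All traces must carry the same event
#'   label sequence.
#' @param discard_s,window_s passed to [segmentStates()].
#'
#' @return data.frame (the flux state table): `sample_id`, `group`,
#'   `state`, `jo2`, `n_replicates`, `analyte` (`"O2"`), `scheme`
#'   (`"wet_weight"` or `"per_cell"`), `units`. Samples with a single
#'   replicate are passed through with a warning.
#' @export
buildStateTable <- function(traces, discard_s = 30, window_s = 60) {
  evsig <- vapply(traces, function(tr) paste(tr@events$label, collapse = ","),
                  character(1))
  if (length(unique(evsig)) != 1L)
    stop("traces mix protocols (event sequences differ): ",
         paste(unique(evsig), collapse = " | "))
  rep_rows <- lapply(traces, function(tr) {
    seg <- segmentStates(tr, discard_s, window_s)
    jo2 <- rep(NA_real_, nrow(seg))
    ok <- !seg$missing
    jo2[ok] <- vapply(which(ok), function(k)
      estimateJO2(tr, c(seg$i_start[k], seg$i_end[k])), numeric(1))
    data.frame(sample_id = tr@sampleId, group = tr@group,
               replicate_id = tr@replicateId, state = seg$state,
               jo2 = jo2, missing = seg$missing,
               amount_units = tr@amountUnits, row.names = NULL)
  })
  reps <- do.call(rbind, rep_rows)
  agg <- stats::aggregate(jo2 ~ sample_id + group + state + amount_units,
                          data = reps, FUN = mean, na.action = stats::na.omit)
  nrep <- stats::aggregate(replicate_id ~ sample_id + group + state + amount_units,
                           data = reps,
                           FUN = function(x) length(unique(x)))
  names(nrep)[names(nrep) == "replicate_id"] <- "n_replicates"
  tab <- merge(agg, nrep,
               by = c("sample_id", "group", "state", "amount_units"))
  if (any(tab$n_replicates < 2))
    warning("sample(s) with a single technical replicate: ",
            paste(unique(tab$sample_id[tab$n_replicates < 2]), collapse = ", "))
  per_mg <- tab$amount_units == "mg_wet_weight"
  tab$analyte <- "O2"
  tab$scheme <- ifelse(per_mg, "wet_weight", "per_cell")
  tab$units <- ifelse(per_mg, "pmol_O2_s-1_mg-1", "pmol_O2_s-1_1e6cells-1")
  tab$amount_units <- NULL
  # preserve ladder order within sample
  state_order <- unique(reps$state)
  tab <- tab[order(tab$group, tab$sample_id,
                   match(tab$state, state_order)), ]
  rownames(tab) <- NULL
  attr(tab, "replicates") <- reps
  tab
}

#' OXPHOS coupling and integrity metrics
#'
#' Per-sample summary of the inhibitor/cytochrome-c segments of a coupling
#' protocol: `omy_inhibition_pct = 100 * (1 - J_OMY / J_PMDGS)` (share of
#' maximal CI+CII respiration abolished by oligomycin),
#' `residual_pct = 100 * J_AMA_ROT / J_PMDGS` (non-mitochondrial residual
#' after antimycin A + rotenone), and, when a cytochrome c state is
#' present, `cc_response_pct = 100 * (J_withCC - J_preCC) / J_preCC`
#' (outer-membrane integrity check).
#'
#' @param stateTable a flux state table from [buildStateTable()], containing
#'   `PMDGS` and `OMY` states (`AMA_ROT` and a `...C` state optional).
#' @return data.frame with one row per sample: `sample_id`, `group`,
#'   `omy_inhibition_pct`, `residual_pct`, `cc_response_pct`.
#' @export
couplingMetrics <- function(stateTable) {
  need <- c("PMDGS", "OMY")
  if (!all(need %in% stateTable$state))
    stop("state table must contain PMDGS and OMY states")
  wide <- function(st) {
    x <- stateTable[stateTable$state == st, c("sample_id", "jo2")]
    stats::setNames(x$jo2, x$sample_id)
  }
  jmax <- wide("PMDGS")
  if (any(jmax <= 0, na.rm = TRUE))
    stop("J_PMDGS must be positive for coupling metrics")
  jomy <- wide("OMY")[names(jmax)]
  jres <- if ("AMA_ROT" %in% stateTable$state)
    wide("AMA_ROT")[names(jmax)] else rep(NA_real_, length(jmax))
  # a cytochrome-c state is a label ending in C whose prefix is itself a
  # measured state (e.g. PMDGSC after PMDGS); this excludes PC-substrate
  # labels such as MPC, whose prefix MP is not a state
  cand <- grep("C$", unique(stateTable$state), value = TRUE)
  cc_state <- cand[sub("C$", "", cand) %in% stateTable$state]
  jcc <- jpre <- rep(NA_real_, length(jmax))
  if (length(cc_state)) {
    jcc <- wide(cc_state[1L])[names(jmax)]
    jpre <- wide(sub("C$", "", cc_state[1L]))[names(jmax)]
  }
  grp <- stateTable$group[match(names(jmax), stateTable$sample_id)]
  data.frame(sample_id = names(jmax), group = grp,
             omy_inhibition_pct = 100 * (1 - jomy / jmax),
             residual_pct = 100 * jres / jmax,
             cc_response_pct = 100 * (jcc - jpre) / jpre,
             row.names = NULL)
}
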