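# --- CBC report compilation ---------------------------------------------------

wbc_normal_classes <- c("neutrophil", "lymphocyte", "monocyte",
                        "eosinophil", "basophil")
wbc_abnormal_classes <- c("blast", "immature_granulocyte",
                          "atypical_lymphocyte", "nrbc")
diff_prefix <- c(neutrophil = "NEUT", lymphocyte = "LYMPH",
                 monocyte = "MONO", eosinophil = "EOS", basophil = "BASO")

#' Compile the 19-parameter CBC report
#'
#' Concentrations follow from counted events over the blood-equivalent volume
#' imaged; derived indices follow the standard identities
#' HCT = RBC x MCV / 10, MCH = 10 x HGB / RBC, MCHC = 100 x HGB / HCT.
#' Nucleated red cells are excluded from the white-cell concentration (they
#' raise a flag instead); the five-part differential is taken over the five
#' normal classes, so its percentages sum to 100 and each absolute count is
#' WBC x pct / 100 by construction. Reported values are rounded for display
#' (concentrations and HGB to 2 decimals, percentages and indices to 1);
#' unrounded values are kept alongside.
#'
#' @param rbc An \code{rbc_indices} from \code{\link{aggregate_rbc}} or NULL
#'   (missing pipeline: RBC-derived measurands are invalidated, the rest are
#'   still reported).
#' @param wbc_counts Named integer vector of classified cells per class
#'   (the nine-class vocabulary), or NULL.
#' @param plt_count Accepted platelet count (scalar), or NULL.
#' @param hgb Hemoglobin estimate from \code{\link{estimate_hgb}}, g/dl, or
#'   NULL.
#' @param geom,kit Chamber geometry and kit configuration.
#' @param n_fields Number of fields analyzed.
#' @param thresholds \code{\link{flag_thresholds}} for the flag rules.
#' @param rules \code{\link{failsafe_rules}} for validity.
#' @param focus Optional focus-proxy statistic (median over fields).
#' @return Object of class \code{cbc_report}: \code{parameters} (named,
#'   display-rounded), \code{raw} (unrounded), \code{flags},
#'   \code{validity}, \code{counts}.
#' @export
compile_cbc <- function(rbc = NULL, wbc_counts = NULL, plt_count = NULL,
                        hgb = NULL, geom, kit, n_fields = geom$n_fields,
                        thresholds = flag_thresholds(),
                        rules = failsafe_rules(), focus = NULL) {
  vol_ul <- imaged_blood_volume(geom, kit, n_fields)
  p <- list()
  counts <- list(n_fields = n_fields,
                 wbc_counts = wbc_counts,
                 n_rbc = if (!is.null(rbc)) rbc$n_cells_counted else 0L,
                 n_rbc_measured = if (!is.null(rbc)) rbc$n_cells_measured else 0L,
                 n_plt = plt_count %||% 0L,
                 focus = focus)

  if (!is.null(wbc_counts)) {
    wc <- setNames(numeric(9), c(wbc_normal_classes, wbc_abnormal_classes))
    wc[names(wbc_counts)] <- wbc_counts
    n_wbc <- sum(wc) - wc[["nrbc"]]      # NRBC excluded from the WBC count
    p$WBC <- n_wbc / (vol_ul * 1e3)
    n5 <- sum(wc[wbc_normal_classes])
    for (cl in wbc_normal_classes) {
      pc <- if (n5 > 0) 100 * wc[[cl]] / n5 else NA_real_
      p[[paste0(diff_prefix[[cl]], "%")]] <- pc
      p[[paste0(diff_prefix[[cl]], "#")]] <- p$WBC * pc / 100
    }
  }
  if (!is.null(rbc) && !is.na(rbc$rbc_conc)) {
    p$RBC <- rbc$rbc_conc
    p$MCV <- rbc$mcv
    p$RDW <- rbc$rdw
  }
  if (!is.null(plt_count)) p$PLT <- plt_count / (vol_ul * 1e3)
  if (!is.null(hgb)) p$HGB <- hgb
  if (!is.null(p$RBC) && !is.null(p$MCV)) p$HCT <- p$RBC * p$MCV / 10
  if (!is.null(p$HGB) && !is.null(p$RBC) && p$RBC > 0)
    p$MCH <- 10 * p$HGB / p$RBC
  if (!is.null(p$HGB) && !is.null(p$HCT) && p$HCT > 0)
    p$MCHC <- 100 * p$HGB / p$HCT

  order19 <- c("WBC", "RBC", "PLT", "HGB", "HCT", "MCV", "RDW", "MCH", "MCHC",
               paste0(rep(diff_prefix, each = 2), c("%", "#")))
  raw <- setNames(rep(NA_real_, length(order19)), order19)
  raw[names(p)] <- unlist(p)
  disp <- raw
  two <- c("WBC", "RBC", "PLT", "HGB", paste0(diff_prefix, "#"))
  disp[two] <- round(raw[two], 2)
  disp[setdiff(order19, two)] <- round(raw[setdiff(order19, two)], 1)

  report <- structure(list(parameters = disp, raw = raw, flags = character(0),
                           validity = NULL, counts = counts),
                      class = "cbc_report")
  report$flags <- apply_flags(report, wbc_counts, thresholds)
  report$validity <- failsafe_check(report, rules)
  report
}

#' Apply white-cell abnormality flags
#'
#' A morphological flag (nrbc, blast, immature_granulocyte,
#' atypical_lymphocyte) is raised when its class reaches both the minimum
#' cell count and the minimum fraction of classified white cells; the
#' distributional flag is raised when any five-part percentage leaves its
#' reference range. Raising an abnormal count never removes its flag.
#'
#' @param report A \code{cbc_report} (for the differential percentages).
#' @param wbc_counts Named classified-cell counts.
#' @param thresholds \code{\link{flag_thresholds}}.
#' @return Character vector of raised flags.
#' @export
apply_flags <- function(report, wbc_counts, thresholds = flag_thresholds()) {
  flags <- character(0)
  if (!is.null(wbc_counts) && sum(wbc_counts) > 0) {
    total <- sum(wbc_counts)
    for (cl in wbc_abnormal_classes) {
      n <- wbc_counts[[cl]] %||% 0
      if (is.na(n)) n <- 0
      if (n >= thresholds$min_cells && n / total >= thresholds$min_fraction)
        flags <- c(flags, cl)
    }
    rr <- thresholds$reference_ranges
    pcts <- report$raw[paste0(names(rr), "%")]
    lo <- vapply(rr, `[`, numeric(1), 1)
    hi <- vapply(rr, `[`, numeric(1), 2)
    if (any(!is.na(pcts) & (pcts < lo | pcts > hi)))
      flags <- c(flags, "distributional_abnormality")
  }
  flags
}

#' Failsafe validity check
#'
#' Verdicts, not exceptions: the run is invalid overall when too few fields
#' were analyzed or the focus proxy is below its floor; individual measurands
#' are invalidated when too few events support them (fewer than
#' \code{min_wbc_events} classified white cells invalidates the whole
#' differential; fewer than \code{min_class_events} of one class invalidates
#' that class's percentage and count while the rest are still reported).
#'
#' @param report A \code{cbc_report}.
#' @param rules \code{\link{failsafe_rules}}.
#' @return List: \code{valid} (overall), \code{reasons} (character),
#'   \code{invalid_measurands} (named character vector measurand -> reason).
#' @export
failsafe_check <- function(report, rules = failsafe_rules()) {
  counts <- report$counts
  reasons <- character(0)
  inv <- character(0)
  if (counts$n_fields < rules$min_fields)
    reasons <- c(reasons, "insufficient fields")
  if (!is.null(counts$focus) && counts$focus < rules$min_focus)
    reasons <- c(reasons, "focus proxy below floor")
  wc <- counts$wbc_counts
  if (is.null(wc) || sum(wc) == 0) {
    inv[c("WBC", paste0(rep(diff_prefix, each = 2), c("%", "#")))] <-
      "no white-cell pipeline output"
  } else {
    n_wbc <- sum(wc)
    if (n_wbc < rules$min_wbc_events) {
      inv[paste0(rep(diff_prefix, each = 2), c("%", "#"))] <-
        sprintf("differential requires >= %d classified cells (got %d)",
                rules$min_wbc_events, n_wbc)
    } else {
      for (cl in wbc_normal_classes) {
        n <- wc[[cl]] %||% 0
        if (is.na(n)) n <- 0
        if (n < rules$min_class_events)
          inv[paste0(diff_prefix[[cl]], c("%", "#"))] <-
            sprintf("subclass requires >= %d events (got %d)",
                    rules$min_class_events, n)
      }
    }
  }
  if (counts$n_rbc < rules$min_rbc_events)
    inv[c("RBC", "MCV", "RDW", "HCT", "MCH", "MCHC")] <-
      sprintf("red-cell count below %d events", rules$min_rbc_events)
  if ((counts$n_plt %||% 0) < rules$min_plt_events)
    inv["PLT"] <- sprintf("platelet count below %d events",
                          rules$min_plt_events)
  nas <- names(report$raw)[is.na(report$raw)]
  nas <- setdiff(nas, names(inv))
  if (length(nas)) inv[nas] <- "missing pipeline output"
  list(valid = length(reasons) == 0, reasons = reasons,
       invalid_measurands = inv)
}

#' @export
print.cbc_report <- function(x, ...) {
  units <- c(WBC = "10^3/ul", RBC = "10^6/ul", PLT = "10^3/ul",
             HGB = "g/dl", HCT = "%", MCV = "fl", RDW = "%", MCH = "pg",
             MCHC = "g/dl",
             setNames(rep(c("%", "10^3/ul"), 5),
                      paste0(rep(diff_prefix, each = 2), c("%", "#"))))
  cat("Complete blood count (", x$counts$n_fields, " fields)\n", sep = "")
  cat(sprintf("  overall: %s\n",
              if (x$validity$valid) "VALID"
              else paste("INVALID -", paste(x$validity$reasons, collapse = "; "))))
  inv <- x$validity$invalid_measurands
  for (nm in names(x$parameters)) {
    v <- x$parameters[[nm]]
    note <- if (nm %in% names(inv)) paste0("  [invalidated: ", inv[[nm]], "]")
            else ""
    cat(sprintf("  %-7s %10s %-9s%s\n", nm,
                ifelse(is.na(v), "--", format(v)), units[[nm]], note))
  }
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Render a report as JSON
#'
#' @param report A \code{cbc_report}.
#' @param path Optional output path; otherwise the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
cbc_report_json <- function(report, path = NULL) {
  obj <- list(parameters = as.list(report$parameters),
              flags = report$flags,
              validity = report$validity,
              counts = report$counts[c("n_fields", "n_rbc", "n_plt")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
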