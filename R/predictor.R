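#' Predictor configuration
#'
#' Cutoffs for the four per-feature calls and the subset of predictors
#' whose conjunction forms the combined call.  Defaults are the Youden
#' (maximum TPR - FPR) operating points estimated on the native insertion
#' site set: a site is called positive when its active-site/dimer-interface
#' distance is strictly below 14.1 Angstrom, its cassette SVM score is
#' strictly above 0, its secondary structure/loop junction distance is at
#' most 2 residues, and its conservation rank is strictly above 0.61.  The
#' default combined rule requires the three strong predictors
#' (conservation, SVM, distance) jointly.
#'
#' @param distance_cutoff Angstrom, positive call when distance < cutoff.
#' @param svm_cutoff positive call when SVM score > cutoff.
#' @param junction_cutoff residues, positive call when junction distance
#'   <= cutoff.
#' @param conservation_cutoff rank, positive call when rank > cutoff.
#' @param combined_rule character subset of
#'   `c("conservation", "svm", "distance", "junction")`.
#' @return object of class `predictor_config`.
#' @export
predictor_config <- function(distance_cutoff = 14.1, svm_cutoff = 0,
                             junction_cutoff = 2, conservation_cutoff = 0.61,
                             combined_rule = c("conservation", "svm", "distance")) {
  cuts <- c(distance_cutoff, svm_cutoff, junction_cutoff, conservation_cutoff)
  if (any(!is.finite(cuts))) stopf("cutoffs must be finite")
  known <- c("conservation", "svm", "distance", "junction")
  combined_rule <- unique(as.character(combined_rule))
  if (!length(combined_rule) || !all(combined_rule %in% known)) {
    stopf("combined_rule must be a non-empty subset of: %s",
          paste(known, collapse = ", "))
  }
  structure(list(distance_cutoff = distance_cutoff,
                 svm_cutoff = svm_cutoff,
                 junction_cutoff = junction_cutoff,
                 conservation_cutoff = conservation_cutoff,
                 combined_rule = combined_rule),
            class = "predictor_config")
}

#' @export
print.predictor_config <- function(x, ...) {
  cat("<predictor_config>\n")
  cat(sprintf("  distance     < %g Angstrom\n", x$distance_cutoff))
  cat(sprintf("  SVM score    > %g\n", x$svm_cutoff))
  cat(sprintf("  junction     <= %g residues\n", x$junction_cutoff))
  cat(sprintf("  conservation > %g\n", x$conservation_cutoff))
  cat(sprintf("  combined rule: %s\n", paste(x$combined_rule, collapse = " & ")))
  invisible(x)
}

feature_calls <- function(distance, svm_score, junction, conservation, config) {
  list(distance = if (is.na(distance)) NA else distance < config$distance_cutoff,
       svm = if (is.na(svm_score)) NA else svm_score > config$svm_cutoff,
       junction = if (is.na(junction)) NA else junction <= config$junction_cutoff,
       conservation = if (is.na(conservation)) NA else conservation > config$conservation_cutoff)
}

#' Call a single site against the predictor cutoffs
#'
#' @param features list or one-row data frame with (a subset of) elements
#'   `distance`, `svm_score`, `junction`, `conservation`; missing or `NA`
#'   entries are treated as absent features.
#' @param config a [predictor_config()].
#' @param missing_action `"error"` (default): a feature required by the
#'   combined rule but absent is an error naming the feature;
#'   `"fail"`: the absent feature simply fails its call (conservative) and
#'   is listed in the verdict's `missing` element.
#' @return object of class `site_verdict`: list with the four per-predictor
#'   calls, `combined`, `missing`, and the input `features`.
#' @examples
#' call_site(list(distance = 8.15, svm_score = 0.34, junction = 2,
#'                conservation = 0.91), predictor_config())
#' @export
call_site <- function(features, config = predictor_config(),
                      missing_action = c("error", "fail")) {
  missing_action <- match.arg(missing_action)
  stopifnot(inherits(config, "predictor_config"))
  get <- function(name) {
    v <- features[[name]]
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }
  f <- list(distance = get("distance"), svm_score = get("svm_score"),
            junction = get("junction"), conservation = get("conservation"))
  calls <- feature_calls(f$distance, f$svm_score, f$junction, f$conservation, config)
  missing <- names(calls)[is.na(calls)]
  required_missing <- intersect(config$combined_rule, missing)
  if (length(required_missing) && missing_action == "error") {
    stopf("missing feature required by the combined rule: %s",
          paste(required_missing, collapse = ", "))
  }
  combined <- all(vapply(config$combined_rule,
                         function(p) isTRUE(calls[[p]]), logical(1)))
  structure(list(calls = calls, combined = combined, missing = missing,
                 features = f),
            class = "site_verdict")
}

#' @export
print.site_verdict <- function(x, ...) {
  mark <- function(v) if (is.na(v)) "absent" else if (v) "+" else "-"
  cat(sprintf("<site_verdict> distance %s | svm %s | junction %s | conservation %s => combined %s\n",
              mark(x$calls$distance), mark(x$calls$svm),
              mark(x$calls$junction), mark(x$calls$conservation),
              if (x$combined) "POSITIVE" else "negative"))
  invisible(x)
}

# Default cutoff grids of the ROC sweeps, one per feature.
default_roc_grids <- function() {
  list(distance = seq(0, 30, by = 0.1),
       svm = seq(-10, 10, by = 0.01),
       junction = 0:5,
       conservation = seq(0, 1, by = 0.01))
}

#' Run the packaged case study
#'
#' Applies the four per-feature cutoff calls and the combined rule to a
#' labelled site feature table (by default the bundled [xynb_sites()]
#' table) and evaluates each predictor against the experimental splicing
#' labels: confusion counts/rates per predictor, the combined-rule site
#' list, and an ROC sweep per feature.
#'
#' @param table site feature table with columns `site`, `distance`,
#'   `svm_score`, `junction`, `conservation`, `splicing`.
#' @param config a [predictor_config()].
#' @return object of class `case_study`: list with `table` (input plus
#'   per-site calls), `confusion` (per predictor), `combined_sites`,
#'   `roc` (per predictor), `config`.
#' @examples
#' cs <- run_case_study()
#' cs$combined_sites
#' @export
run_case_study <- function(table = xynb_sites(), config = predictor_config()) {
  if (!is.data.frame(table) || !nrow(table)) stopf("empty site feature table")
  need <- c("site", "distance", "svm_score", "junction", "conservation", "splicing")
  if (!all(need %in% names(table))) {
    stopf("feature table needs columns: %s", paste(need, collapse = ", "))
  }
  unlabeled <- is.na(table$splicing)
  if (any(unlabeled)) {
    warnf("excluding %d unlabeled row(s) from the case study", sum(unlabeled))
    table <- table[!unlabeled, , drop = FALSE]
  }
  if (!nrow(table)) stopf("no labelled rows left in the feature table")

  calls <- data.frame(
    distance = table$distance < config$distance_cutoff,
    svm = table$svm_score > config$svm_cutoff,
    junction = table$junction <= config$junction_cutoff,
    conservation = table$conservation > config$conservation_cutoff
  )
  combined <- rep(TRUE, nrow(table))
  for (p in config$combined_rule) combined <- combined & calls[[p]]

  confusion <- lapply(c(distance = "distance", svm = "svm",
                        junction = "junction", conservation = "conservation"),
                      function(p) confusion_rates(table$splicing, calls[[p]]))
  confusion$combined <- confusion_rates(table$splicing, combined)

  grids <- default_roc_grids()
  roc <- list(
    distance = roc_sweep(table$distance, table$splicing, grids$distance, "less"),
    svm = roc_sweep(table$svm_score, table$splicing, grids$svm, "greater"),
    junction = roc_sweep(table$junction, table$splicing, grids$junction, "leq"),
    conservation = roc_sweep(table$conservation, table$splicing,
                             grids$conservation, "greater")
  )
  out <- cbind(table, calls, combined = combined)
  structure(list(table = out, confusion = confusion,
                 combined_sites = table$site[combined],
                 roc = roc, config = config),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %d labelled sites (%d splicers)\n",
              nrow(x$table), sum(x$table$splicing)))
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%d%%", round(100 * v))
  for (p in c("distance", "svm", "junction", "conservation", "combined")) {
    cr <- x$confusion[[p]]
    cat(sprintf("  %-12s TP %2d  FN %2d  FP %2d  TN %2d   TPR %4s  FPR %4s\n",
                p, cr$TP, cr$FN, cr$FP, cr$TN, pct(cr$TPR), pct(cr$FPR)))
  }
  cat("  combined-rule sites:",
      if (length(x$combined_sites)) paste(x$combined_sites, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' End-to-end site prediction for one extein
#'
#' Enumerates candidate C/S/T sites and computes every feature whose inputs
#' are available: conservation rank (needs a PSSM), cassette SVM score
#' (needs a fitted model), active-site/dimer-interface distance and
#' junction distance (need a structure context with annotations and
#' secondary-structure codes), plus C-beta density and snapshot flexibility
#' when possible.  Features with missing inputs are reported absent and
#' conservatively fail their call.  Sites are ranked by the number of
#' satisfied predictors, ties broken by conservation rank.
#'
#' @param extein an [extein_record].
#' @param pssm optional [pssm] for the extein sequence.
#' @param model optional [fit_cassette_svm()] model.
#' @param structure optional [structure_context] in extein numbering.
#' @param snapshots optional [snapshot_set] for flexibility.
#' @param config a [predictor_config()].
#' @return object of class `site_report`: data frame of per-site features,
#'   calls, `n_satisfied` and `combined`, sorted by rank; attribute
#'   `"config"`.
#' @export
predict_extein <- function(extein, pssm = NULL, model = NULL,
                           structure = NULL, snapshots = NULL,
                           config = predictor_config()) {
  stopifnot(inherits(extein, "extein_record"))
  n <- length(extein$residues)
  if (!is.null(pssm)) {
    if (nrow(pssm$probabilities) != n) {
      stopf("PSSM has %d positions but extein '%s' has %d residues",
            nrow(pssm$probabilities), extein$id, n)
    }
  }
  if (!is.null(structure)) {
    bad <- structure$positions[structure$positions < 1L | structure$positions > n]
    if (length(bad)) {
      stopf("structure position %d outside extein '%s' numbering 1..%d",
            bad[1L], extein$id, n)
    }
  }
  cand <- enumerate_candidate_sites(extein)
  if (!nrow(cand)) {
    message(sprintf("extein '%s': no candidate C/S/T sites with a full cassette window",
                    extein$id))
    out <- cbind(cand, distance = numeric(0), svm_score = numeric(0),
                 junction = numeric(0), conservation = numeric(0))
    return(structure(out, class = c("site_report", "data.frame"), config = config))
  }
  m <- nrow(cand)
  na <- rep(NA_real_, m)
  feat <- data.frame(distance = na, svm_score = na, junction = na,
                     conservation = na, cbeta_density = na, flexibility = na)

  if (!is.null(pssm) && m >= 2L) {
    prof <- entropy_profile(pssm)
    feat$conservation <- vapply(cand$position, function(p) {
      conservation_rank(prof, cand$position, p)
    }, numeric(1))
  }
  if (!is.null(model)) {
    cass <- lapply(cand$position, function(p) extract_cassette(extein, p))
    feat$svm_score <- predict(model, cass)
  }
  if (!is.null(structure)) {
    has_ann <- length(structure$active_site) + length(structure$dimer_interface) > 0
    groups <- if (!is.null(structure$ss_codes)) group_ss_codes(structure$ss_codes) else NULL
    for (k in seq_len(m)) {
      p <- cand$position[k]
      if (has_ann && p %in% structure$positions) {
        feat$distance[k] <- distance_to_functional_site(structure, p, "either")
      }
      if (p %in% structure$positions) {
        feat$cbeta_density[k] <- cbeta_density(structure, p)
      }
      if (!is.null(groups) && as.character(p) %in% names(groups)) {
        feat$junction[k] <- classify_site_ss(groups, p)$junction_distance
      }
    }
  }
  if (!is.null(snapshots)) {
    ok <- cand$position %in% snapshots$positions
    feat$flexibility[ok] <- vapply(cand$position[ok], function(p) {
      site_flexibility(snapshots, p)
    }, numeric(1))
  }

  calls <- t(vapply(seq_len(m), function(k) {
    v <- call_site(feat[k, ], config, missing_action = "fail")
    c(distance = v$calls$distance, svm = v$calls$svm,
      junction = v$calls$junction, conservation = v$calls$conservation,
      combined = v$combined)
  }, logical(5)))
  n_satisfied <- rowSums(calls[, 1:4, drop = FALSE], na.rm = TRUE)

  out <- cbind(cand, feat, as.data.frame(calls), n_satisfied = n_satisfied)
  ord <- order(-out$n_satisfied,
               -ifelse(is.na(out$conservation), -1, out$conservation),
               out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("site_report", "data.frame"), config = config)
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %d candidate site(s)\n", nrow(x)))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$junction <- ifelse(is.na(df$junction), NA,
                          ifelse(df$junction > 2, ">2", df$junction))
    show <- c("position", "plus_one_residue", "distance", "svm_score",
              "junction", "conservation", "n_satisfied", "combined")
    print.data.frame(df[, show], digits = 3, row.names = FALSE)
  }
  invisible(x)
}
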