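# Real-trial mode: read a patient-level export and replay the sequential
# enrichment rules on it, the way a monitoring committee would have applied
# them — interim analyses at fixed cumulative enrollment counts, enrichment
# restricting which later patients enter the analysis set.

#' Read a patient-level trial CSV
#'
#' Expects one row per patient with an id column, an enrollment-order or
#' date column, binary arm and outcome columns, and one column per declared
#' biomarker partition assigning each patient a subset label.  Records are
#' sorted by enrollment (stable: file order breaks ties).
#'
#' @param path CSV file path.
#' @param id,arm,outcome column names (defaults `"id"`, `"arm"`,
#'   `"outcome"`).
#' @param order name of a numeric enrollment-order column (default
#'   `"enroll_order"`), or `NULL` when `date` is given.
#' @param date optional name of an enrollment-date column (parsed with
#'   [as.Date()]); overrides `order`.
#' @param partitions character vector of partition column names; defaults
#'   to every remaining column.
#' @return An object of class `trial_dataset`: `records` (sorted data
#'   frame) and `partitions`.
#' @export
read_trial_csv <- function(path, id = "id", order = "enroll_order",
                           date = NULL, arm = "arm", outcome = "outcome",
                           partitions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(id, if (is.null(date)) order else date, arm, outcome)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[[id]])) {
    stop("duplicate patient id(s): ",
         paste(unique(df[[id]][duplicated(df[[id]])]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c(arm, outcome)) {
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      stop(sprintf("non-binary value '%s' in column '%s' at row %d",
                   df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
  }
  if (is.null(partitions)) partitions <- setdiff(names(df), needed)
  if (!length(partitions)) {
    stop("no partition column found or declared", call. = FALSE)
  }
  missing_p <- setdiff(partitions, names(df))
  if (length(missing_p)) {
    stop("missing partition column(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  for (p in partitions) {
    if (anyNA(df[[p]]) || any(df[[p]] == "")) {
      stop(sprintf("unlabeled patients in partition '%s'", p), call. = FALSE)
    }
  }
  key <- if (!is.null(date)) as.Date(df[[date]]) else {
    if (!is.numeric(df[[order]])) {
      stop(sprintf("enrollment order column '%s' must be numeric", order),
           call. = FALSE)
    }
    df[[order]]
  }
  if (anyNA(key)) stop("unparseable enrollment order/date", call. = FALSE)
  df <- df[order(key), , drop = FALSE]  # stable: ties keep file order
  rownames(df) <- NULL
  out <- data.frame(id = df[[id]], arm = as.integer(df[[arm]]),
                    outcome = as.integer(df[[outcome]]),
                    stringsAsFactors = FALSE)
  out[partitions] <- lapply(df[partitions], as.character)
  structure(list(records = out, partitions = partitions),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Trial dataset: %d patients, partitions: %s\n",
              nrow(x$records), paste(x$partitions, collapse = ", ")))
  invisible(x)
}

#' Build a trial dataset from in-memory records
#'
#' Convenience constructor for records already in enrollment order (e.g.
#' from [run_trial()] with `keep_patients = TRUE`): the `subset` column
#' becomes a single partition.
#'
#' @param records data frame with columns `subset`, `arm`, `outcome`, in
#'   enrollment order.
#' @param partition name for the partition (default `"subset"`).
#' @return A `trial_dataset`.
#' @export
as_trial_dataset <- function(records, partition = "subset") {
  stopifnot(all(c("subset", "arm", "outcome") %in% names(records)))
  out <- data.frame(id = seq_len(nrow(records)),
                    arm = as.integer(records$arm),
                    outcome = as.integer(records$outcome),
                    stringsAsFactors = FALSE)
  out[[partition]] <- as.character(records$subset)
  structure(list(records = out, partitions = partition),
            class = "trial_dataset")
}

#' Replay the sequential enrichment rules on a trial dataset
#'
#' At each analysis of the calendar, the analysis set grows to the next
#' patients in enrollment order; after an enrichment only patients from the
#' enriched subset(s) enter (unless no such patients remain).  Decisions
#' use [evaluate_analysis()] on the active subsets; estimates of dropped
#' subsets stay frozen at their enrichment-look values.
#'
#' @param dataset a [read_trial_csv()] or [as_trial_dataset()] result.
#' @param partition which partition to analyse.
#' @param calendar strictly increasing cumulative enrolled-patient counts
#'   at which analyses occur; the last entry must not exceed the dataset
#'   size.
#' @param thresholds an [enrich_thresholds()] object.
#' @param prior Beta prior.
#' @param n_draws posterior draws per analysis.
#' @param seed integer master seed (per-analysis draw seeds are derived
#'   from it, as in [run_trial()]).
#' @param global_method passed to [sample_posterior()].
#' @return An object of class `trial_analysis`: `per_look` (long data
#'   frame: one row per analysis x subset plus a `global` row, with
#'   estimates, credibility intervals, influence and interaction
#'   probabilities, and the decision), `decisions` (per-analysis
#'   classification labels), `enrichment_look`, `enriched_subsets`.
#' @export
analyze_trial <- function(dataset, partition, calendar, thresholds,
                          prior = beta_params(1, 1), n_draws = 10000,
                          seed = 1L,
                          global_method = c("pooled", "weighted")) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(thresholds, "enrich_thresholds"))
  global_method <- match.arg(global_method)
  if (!partition %in% dataset$partitions) {
    stop("unknown partition: ", partition, call. = FALSE)
  }
  if (any(diff(calendar) <= 0) || any(calendar < 1)) {
    stop("'calendar' must be strictly increasing positive counts",
         call. = FALSE)
  }
  records <- dataset$records
  records$subset <- records[[partition]]
  if (calendar[length(calendar)] > nrow(records)) {
    stop("calendar exceeds the number of available patients", call. = FALSE)
  }
  subsets <- sort(unique(records$subset))
  if (length(subsets) < 2L) {
    stop("the partition must define at least 2 subsets", call. = FALSE)
  }
  state <- list(active = subsets, frozen = FALSE)
  pool <- seq_len(nrow(records))   # indices not yet in the analysis set
  taken <- integer(0)
  enrichment_look <- NA_integer_
  frozen_rows <- NULL
  decisions <- character(length(calendar))
  per_look <- list()
  for (a in seq_along(calendar)) {
    need <- calendar[a] - length(taken)
    eligible <- if (state$frozen) {
      pool[records$subset[pool] %in% state$active]
    } else pool
    add <- utils::head(eligible, max(need, 0))
    taken <- c(taken, add)
    pool <- setdiff(pool, add)
    current <- records[sort(taken), , drop = FALSE]
    counts <- count_records(current, subsets)
    evaluable <- !state$frozen && length(state$active) >= 2L
    dec <- NULL
    if (evaluable) {
      dec <- evaluate_analysis(counts, state$active, thresholds, prior,
                               n_draws,
                               seed = derive_seed(seed, .STREAM_DRAWS, a),
                               global_method = global_method)
      if (dec$action == "enrich") {
        state <- update_enrichment_state(state, dec)
        enrichment_look <- a
      }
    }
    est_draws <- sample_posterior(counts, prior, n_draws,
                                  seed = derive_seed(seed, 4L, a),
                                  global_method = global_method)
    est <- posterior_estimates(est_draws)
    if (!is.null(frozen_rows)) {
      dropped <- setdiff(subsets, state$active)
      keep <- est$subset %in% dropped
      est[keep, ] <- frozen_rows[frozen_rows$subset %in% dropped, ]
    }
    if (a == enrichment_look && !is.na(enrichment_look)) frozen_rows <- est
    decisions[a] <- if (is.na(enrichment_look)) "entire_population"
                    else classification_label(state$active)
    row <- est
    row$look <- a
    row$n <- c(colSums(counts$totals), sum(counts$totals))
    row$P1 <- NA_real_; row$P2 <- NA_real_
    row$P_quali <- NA_real_; row$P_quanti <- NA_real_
    if (!is.null(dec)) {
      m <- match(dec$evidence$subset, row$subset)
      row$P1[m] <- dec$evidence$P1
      row$P2[m] <- dec$evidence$P2
      row$P_quali[m] <- dec$evidence$P_quali
      row$P_quanti[m] <- dec$evidence$P_quanti
    }
    row$decision <- if (is.null(dec)) {
      if (is.na(enrichment_look)) "not evaluated"
      else paste("enriched in", classification_label(state$active))
    } else if (dec$action == "enrich") {
      paste("enrich", classification_label(dec$enriched_subsets))
    } else "go with entire population"
    per_look[[a]] <- row
  }
  structure(list(per_look = do.call(rbind, per_look),
                 decisions = decisions,
                 enrichment_look = enrichment_look,
                 enriched_subsets = if (is.na(enrichment_look)) character(0)
                                    else state$active,
                 calendar = calendar, partition = partition,
                 thresholds = thresholds),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Sequential analysis of partition '%s' (%d analyses):\n",
              x$partition, length(x$calendar)))
  if (!is.na(x$enrichment_look)) {
    cat(sprintf("Enrichment in %s at analysis %d\n",
                paste(x$enriched_subsets, collapse = " + "),
                x$enrichment_look))
  } else {
    cat("No enrichment: go with the entire population throughout\n")
  }
  print(x$per_look, digits = 3, row.names = FALSE)
  invisible(x)
}
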