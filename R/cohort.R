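## Cohort builder: longitudinal clinical events -> binary patient-by-feature
## matrix + SAE labels.
##
## Study design implemented here: the index date is the first target-drug
## event (optionally the first one on/after the first qualifying
## diagnosis); the baseline period is strictly before the index date and
## supplies the features; the follow-up window runs from the index date to
## the last target-drug event plus a configurable extension (default 30
## days, both endpoints inclusive) and supplies the SAE label: y = 1 iff
## some follow-up event is flagged as resulting in hospitalization or
## death (optionally restricted to a user-supplied code set).

#' Cohort-building configuration
#'
#' @param target_drug_codes non-empty character vector of drug codes whose
#'   first occurrence defines the index date.
#' @param required_diagnosis_codes optional diagnosis codes; when given,
#'   the index date is the first target-drug event on/after the first
#'   qualifying diagnosis.
#' @param followup_extension_days days added after the last target-drug
#'   event to close the follow-up window (default 30).
#' @param age_bin_width width in years of the uniform age bins (default
#'   10).
#' @param min_prevalence optional minimum fraction of patients a code
#'   feature must reach to be kept (default 0 = keep all).
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(target_drug_codes,
                          required_diagnosis_codes = NULL,
                          followup_extension_days = 30,
                          age_bin_width = 10,
                          min_prevalence = 0) {
  if (length(target_drug_codes) == 0)
    stop("target_drug_codes must be non-empty")
  stopifnot(followup_extension_days >= 0, age_bin_width > 0,
            min_prevalence >= 0, min_prevalence < 1)
  structure(list(target_drug_codes = as.character(target_drug_codes),
                 required_diagnosis_codes = required_diagnosis_codes,
                 followup_extension_days = as.integer(followup_extension_days),
                 age_bin_width = as.integer(age_bin_width),
                 min_prevalence = min_prevalence),
            class = "cohort_config")
}

#' Read a longitudinal clinical event table
#'
#' Expects delimited text with columns `patient_id, date, code_system,
#' code, hospitalization_flag, death_flag` (ISO dates; flags 0/1 or
#' TRUE/FALSE). Rows with unparseable dates or empty codes raise an error
#' naming the row.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame of events with `Date` dates and logical flags.
#' @export
read_events <- function(path, sep = ",") {
  ev <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("patient_id", "date", "code_system", "code",
            "hospitalization_flag", "death_flag")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event file is missing column(s): ", paste(miss, collapse = ", "))
  d <- as.Date(ev$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date at row(s): ",
         paste(head(which(is.na(d)), 5), collapse = ", "))
  ev$date <- d
  if (any(!nzchar(ev$code)))
    stop("empty code at row(s): ",
         paste(head(which(!nzchar(ev$code)), 5), collapse = ", "))
  bad <- !ev$code_system %in% c("diagnosis", "drug", "demographic")
  if (any(bad))
    warning("unknown code_system at ", sum(bad), " row(s); kept as-is")
  ev$hospitalization_flag <- as.logical(ev$hospitalization_flag)
  ev$death_flag <- as.logical(ev$death_flag)
  ev$patient_id <- as.character(ev$patient_id)
  ev$code <- as.character(ev$code)
  ev
}

#' Read a two-column code-mapping table
#'
#' Maps source codes to target categories (e.g. ICD to Phecode, NDC/RxNorm
#' to ATC level 3). One source code maps to at most one target; duplicate
#' or malformed rows raise an error naming the row.
#'
#' @param path file path to delimited text with columns `source, target`
#'   (header optional if named exactly so).
#' @param sep field separator (default comma).
#' @return named character vector: `map["source"] -> target`.
#' @export
read_code_map <- function(path, sep = ",") {
  m <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(m) < 2)
    stop("mapping table must have two columns (source, target)")
  src <- as.character(m[[1]]); tgt <- as.character(m[[2]])
  bad <- !nzchar(src) | !nzchar(tgt) | is.na(src) | is.na(tgt)
  if (any(bad))
    stop("malformed mapping row(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  dup <- duplicated(src)
  if (any(dup))
    stop("duplicate source code(s) in mapping: ",
         paste(head(unique(src[dup]), 5), collapse = ", "))
  setNames(tgt, src)
}

#' Map codes through a lookup table
#'
#' Vectorized lookup; codes absent from the table yield `NA` (the
#' missing-marker) and are counted by the caller. A `NULL` map is the
#' identity.
#'
#' @param codes character vector of source codes.
#' @param map named character vector from [read_code_map()], or `NULL`.
#' @return character vector of mapped categories with `NA` for unmapped
#'   codes; attribute `n_unmapped` carries the miss count.
#' @examples
#' map_codes(c("250.00", "X999"), c("250.00" = "250.2"))
#' @export
map_codes <- function(codes, map = NULL) {
  if (is.null(map)) return(structure(codes, n_unmapped = 0L))
  out <- unname(map[codes])
  structure(out, n_unmapped = sum(is.na(out)))
}

#' Assign per-patient index dates
#'
#' The index date is the earliest event whose code is in
#' `target_drug_codes`; when `required_diagnosis_codes` is set, the
#' earliest such event on/after the first qualifying diagnosis. Patients
#' with no qualifying event get `NA` (excluded, a normal outcome).
#'
#' @param events event data.frame (see [read_events()]).
#' @param config a [cohort_config()].
#' @return named `Date` vector over all patients in `events`; `NA` where
#'   no index date exists.
#' @export
assign_index_date <- function(events, config) {
  pats <- unique(events$patient_id)
  out <- as.Date(setNames(rep(NA_real_, length(pats)), pats),
                 origin = "1970-01-01")
  drug <- events[events$code_system == "drug" &
                   events$code %in% config$target_drug_codes, ]
  if (!is.null(config$required_diagnosis_codes)) {
    dx <- events[events$code_system == "diagnosis" &
                   events$code %in% config$required_diagnosis_codes, ]
    first_dx <- tapply(dx$date, dx$patient_id, min)
    keep <- drug$patient_id %in% names(first_dx) &
      drug$date >= as.Date(first_dx[drug$patient_id],
                           origin = "1970-01-01")
    drug <- drug[keep, ]
  }
  if (nrow(drug)) {
    idx <- tapply(drug$date, drug$patient_id, min)
    out[names(idx)] <- as.Date(idx, origin = "1970-01-01")
  }
  out
}

#' Split events into baseline and follow-up periods
#'
#' Baseline events fall strictly before the index date; the follow-up
#' window is `[index, last target-drug date + extension]`, both endpoints
#' inclusive (the index-date event itself belongs to follow-up, not
#' baseline). Events after the window end are discarded.
#'
#' @param events event data.frame.
#' @param index_date named `Date` vector from [assign_index_date()].
#' @param config a [cohort_config()].
#' @return list with data.frames `baseline` and `followup` and a named
#'   `Date` vector `followup_end`.
#' @export
split_baseline_followup <- function(events, index_date, config) {
  index_date <- index_date[!is.na(index_date)]
  ev <- events[events$patient_id %in% names(index_date), ]
  idx <- index_date[ev$patient_id]
  is_drug <- ev$code_system == "drug" & ev$code %in% config$target_drug_codes
  drug <- ev[is_drug & ev$date >= idx, ]
  last_drug <- tapply(drug$date, drug$patient_id, max)
  fend <- as.Date(last_drug[names(index_date)], origin = "1970-01-01") +
    config$followup_extension_days
  names(fend) <- names(index_date)
  endv <- fend[ev$patient_id]
  list(baseline = ev[ev$date < idx, ],
       followup = ev[ev$date >= idx & ev$date <= endv, ],
       followup_end = fend)
}

#' Label serious adverse events over the follow-up window
#'
#' `y = 1` iff the patient has at least one follow-up event flagged as
#' resulting in hospitalization or death; when `sae_codes` is supplied the
#' flagged event's code must additionally belong to that set.
#'
#' @param followup follow-up event data.frame (from
#'   [split_baseline_followup()]).
#' @param patients character vector of cohort patient ids (defines output
#'   order; patients without follow-up events get 0).
#' @param sae_codes optional character vector of qualifying codes.
#' @return named integer 0/1 vector over `patients`.
#' @export
label_sae <- function(followup, patients, sae_codes = NULL) {
  hit <- followup$hospitalization_flag | followup$death_flag
  if (!is.null(sae_codes)) hit <- hit & followup$code %in% sae_codes
  sae_pats <- unique(followup$patient_id[hit])
  setNames(as.integer(patients %in% sae_pats), patients)
}

#' One-hot encode age into uniform bins
#'
#' Half-open bins `[b, b + width)` starting at 0; exactly one indicator is
#' set. An age on a bin boundary goes to the upper bin.
#'
#' @param age nonnegative age(s) in years.
#' @param width bin width in years (default 10).
#' @param n_bins number of bins (default: enough to cover `max(age)`).
#' @return for a single age, a named 0/1 vector; for a vector of ages, a
#'   matrix with one row per age.
#' @examples
#' discretize_age(77)          # bin [70,80)
#' discretize_age(80)[["age:[80,90)"]]
#' @export
discretize_age <- function(age, width = 10, n_bins = NULL) {
  if (any(age < 0)) stop("age must be nonnegative")
  bin <- floor(age / width)
  n_bins <- n_bins %||% (max(bin) + 1L)
  labs <- sprintf("age:[%d,%d)", width * (seq_len(n_bins) - 1L),
                  width * seq_len(n_bins))
  out <- matrix(0L, length(age), n_bins, dimnames = list(NULL, labs))
  out[cbind(seq_along(age), bin + 1L)] <- 1L
  if (length(age) == 1L) out[1, ] else out
}

## parse "key:value" demographic codes into a per-patient table,
## preferring the latest record on/before the index date
.demographics <- function(events, index_date) {
  dem <- events[events$code_system == "demographic", ]
  dem <- dem[dem$patient_id %in% names(index_date), ]
  kv <- regmatches(dem$code, regexpr(":", dem$code), invert = TRUE)
  dem$key <- vapply(kv, `[`, "", 1L)
  dem$value <- vapply(kv, function(x) if (length(x) > 1) x[2] else NA_character_, "")
  out <- list()
  for (k in c("age", "sex", "race")) {
    sub <- dem[dem$key == k, ]
    picked <- vapply(split(sub, sub$patient_id), function(s) {
      pre <- s$date <= index_date[s$patient_id[1]]
      if (any(pre)) s$value[pre][which.max(as.numeric(s$date[pre]))]
      else s$value[which.min(as.numeric(s$date))]
    }, "")
    out[[k]] <- picked[names(index_date)]
  }
  out
}

#' Build a binary patient-by-feature cohort matrix with SAE labels
#'
#' Runs the full cohort pipeline: index-date assignment (patients without
#' one are excluded and logged), baseline/follow-up split, code mapping
#' (unmapped codes dropped with a logged count), SAE labelling, and
#' assembly of the binary feature matrix. Features are ordered
#' deterministically: demographic one-hots (age bins, sex, race), then
#' sorted diagnosis categories (`dx:` prefix), then sorted drug classes
#' (`rx:` prefix). A code indicator is 1 iff the patient has at least one
#' baseline event mapping to it.
#'
#' @param events event data.frame from [read_events()] or
#'   [simulate_event_stream()].
#' @param config a [cohort_config()].
#' @param diagnosis_map,drug_map optional named vectors from
#'   [read_code_map()] (e.g. ICD to Phecode, drug code to ATC level 3);
#'   `NULL` keeps codes as-is.
#' @param sae_codes optional qualifying code set for SAE labelling.
#' @return object of class `"spfa_cohort"`: binary matrix `X` (features x
#'   patients), labels `y`, `index_date`, `followup_end`, `feature_names`,
#'   `patient_ids`, `exclusions` (data.frame with reasons), and
#'   `unmapped` counts per vocabulary.
#' @export
build_cohort <- function(events, config, diagnosis_map = NULL,
                         drug_map = NULL, sae_codes = NULL) {
  idx <- assign_index_date(events, config)
  excl <- data.frame(patient_id = names(idx)[is.na(idx)],
                     reason = rep("no qualifying index date",
                                  sum(is.na(idx))))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("empty cohort: no patient has an index date")
  pats <- sort(names(idx))
  idx <- idx[pats]
  sp <- split_baseline_followup(events, idx, config)

  base <- sp$baseline
  unmapped <- c(diagnosis = 0L, drug = 0L)
  for (sys in c("diagnosis", "drug")) {
    map <- if (sys == "diagnosis") diagnosis_map else drug_map
    if (is.null(map)) next
    sel <- base$code_system == sys
    mapped <- map_codes(base$code[sel], map)
    unmapped[sys] <- attr(mapped, "n_unmapped")
    base$code[sel] <- as.character(mapped)
    base <- base[!is.na(base$code), ]   # unmapped codes are dropped (logged)
  }

  ## follow-up codes are mapped for sae_codes matching
  fu <- sp$followup
  if (!is.null(sae_codes)) {
    if (!is.null(diagnosis_map)) {
      sel <- fu$code_system == "diagnosis"
      m <- map_codes(fu$code[sel], diagnosis_map)
      fu$code[sel] <- ifelse(is.na(m), fu$code[sel], m)
    }
  }
  y <- label_sae(fu, pats, sae_codes)

  dem <- .demographics(events, idx)
  age <- suppressWarnings(as.numeric(dem$age))
  blocks <- list()
  if (any(!is.na(age))) {
    ab <- discretize_age(ifelse(is.na(age), 0, age), config$age_bin_width)
    if (is.null(dim(ab)))
      ab <- matrix(ab, 1, dimnames = list(NULL, names(ab)))
    ab[is.na(age), ] <- 0L
    blocks$age <- ab
  }
  for (k in c("sex", "race")) {
    v <- dem[[k]]
    lev <- sort(unique(v[!is.na(v)]))
    if (length(lev)) {
      b <- vapply(lev, function(l) as.integer(!is.na(v) & v == l),
                  integer(length(pats)))
      colnames(b) <- paste0(k, ":", lev)
      blocks[[k]] <- b
    }
  }
  for (sys in c("diagnosis", "drug")) {
    pre <- if (sys == "diagnosis") "dx:" else "rx:"
    sel <- base$code_system == sys
    codes <- sort(unique(base$code[sel]))
    if (length(codes)) {
      b <- matrix(0L, length(pats), length(codes),
                  dimnames = list(pats, paste0(pre, codes)))
      hit <- unique(base[sel, c("patient_id", "code")])
      b[cbind(match(hit$patient_id, pats), match(hit$code, codes))] <- 1L
      blocks[[sys]] <- b
    }
  }
  Xp <- do.call(cbind, blocks)   # patients x features
  rownames(Xp) <- pats
  if (config$min_prevalence > 0) {
    keep <- colMeans(Xp) >= config$min_prevalence |
      !grepl("^(dx|rx):", colnames(Xp))
    Xp <- Xp[, keep, drop = FALSE]
  }
  X <- t(Xp)   # features x patients
  structure(list(X = X, y = y, index_date = idx,
                 followup_end = sp$followup_end[pats],
                 feature_names = rownames(X), patient_ids = pats,
                 exclusions = excl, unmapped = unmapped,
                 config = config),
            class = "spfa_cohort")
}

#' @export
print.spfa_cohort <- function(x, ...) {
  cat("SPFA cohort\n")
  cat(sprintf("  patients: %d  (excluded: %d)\n", length(x$patient_ids),
              nrow(x$exclusions)))
  cat(sprintf("  features: %d   SAE prevalence: %.1f%%\n",
              length(x$feature_names), 100 * mean(x$y)))
  if (any(x$unmapped > 0))
    cat(sprintf("  unmapped codes dropped: diagnosis %d, drug %d\n",
                x$unmapped["diagnosis"], x$unmapped["drug"]))
  invisible(x)
}

#' Write / read a cohort as plain-text artifacts
#'
#' The feature matrix goes to sparse matrix-market `matrix.mtx` with
#' sidecar `features.txt` and `patients.txt`, labels and key dates to
#' `labels.csv`.
#'
#' @param cohort an `"spfa_cohort"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(cohort$X, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(cohort$feature_names, file.path(dir, "features.txt"))
  writeLines(cohort$patient_ids, file.path(dir, "patients.txt"))
  write.csv(data.frame(patient_id = cohort$patient_ids, y = cohort$y,
                       index_date = cohort$index_date,
                       followup_end = cohort$followup_end),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  X <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(X) <- "integer"   # pattern matrices read back as logical
  rownames(X) <- readLines(file.path(dir, "features.txt"))
  colnames(X) <- readLines(file.path(dir, "patients.txt"))
  lab <- read.delim(file.path(dir, "labels.csv"), sep = ",",
                    stringsAsFactors = FALSE)
  structure(list(X = X, y = setNames(lab$y, lab$patient_id),
                 index_date = as.Date(setNames(lab$index_date,
                                               lab$patient_id)),
                 followup_end = as.Date(setNames(lab$followup_end,
                                                 lab$patient_id)),
                 feature_names = rownames(X), patient_ids = colnames(X),
                 exclusions = data.frame(patient_id = character(),
                                         reason = character()),
                 unmapped = c(diagnosis = NA_integer_, drug = NA_integer_),
                 config = NULL),
            class = "spfa_cohort")
}
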