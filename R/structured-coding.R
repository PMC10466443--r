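# Structured (coded) SDOH documentation -----------------------------------

#' Normalize an ICD-10-CM code
#'
#' Uppercases, inserts the dot after the 3-character category when absent
#' ("Z5941" -> "Z59.41") and validates the result: one letter, two
#' alphanumerics, then optionally a dot and 1-4 alphanumerics. A bare
#' numeric grouping such as "59.4" is rejected unless a default chapter
#' letter is supplied.
#'
#' @param raw character vector of raw codes.
#' @param default_chapter optional single letter prepended to codes that
#'   start with a digit (coded SDOH tables are sometimes printed without the
#'   "Z" prefix).
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(raw, default_chapter = NULL) {
  stopifnot(is.character(raw), all(nzchar(raw)))
  x <- toupper(gsub("\\s", "", raw, perl = TRUE))
  bare <- grepl("^[0-9]", x)
  if (any(bare)) {
    if (is.null(default_chapter)) {
      stop("malformed ICD-10-CM code(s) without chapter letter: ",
           paste(unique(raw[bare]), collapse = ", "))
    }
    x[bare] <- paste0(toupper(default_chapter), x[bare])
  }
  nodot <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3L
  x[nodot] <- paste0(substr(x[nodot], 1L, 3L), ".", substring(x[nodot], 4L))
  ok <- grepl("^[A-Z][0-9][0-9A-Z](\\.[0-9A-Z]{1,4})?$", x)
  if (!all(ok)) {
    stop("malformed ICD-10-CM code(s): ", paste(unique(raw[!ok]), collapse = ", "))
  }
  x
}

# hierarchical match: code equals the stem or extends it (Z59.4 covers Z59.41)
code_matches_stem <- function(codes, stem) {
  codes == stem | startsWith(codes, stem)
}

#' The packaged SDOH Z-code domain map
#'
#' Z-code groupings for the seven SDOH domains, following the published
#' groupings used for the structured-data arm (e.g. food insecurity: Z59.4,
#' Z59.41; stress: Z63.7, Z63.79, Z73.2, Z73.3). Matching is hierarchical:
#' a record code counts when it equals a listed stem or extends it with
#' further characters.
#'
#' @param widen_z60 if `TRUE`, widen the social-connections grouping from
#'   the listed subcodes (Z60.2, Z60.4, Z60.8) to the whole Z60 category.
#' @param path optional path to a user CSV with columns `domain`,
#'   `code_stem` overriding the packaged map.
#' @return data frame with columns `domain`, `code_stem`.
#' @export
sdoh_code_map <- function(widen_z60 = FALSE, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sdoh_code_map.csv", package = "sdohscan")
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("domain", "code_stem") %in% names(map)),
            all(map$domain %in% sdoh_domains))
  map$code_stem <- normalize_code(map$code_stem)
  if (widen_z60) {
    map <- map[!(map$domain == "social_connections"), , drop = FALSE]
    map <- rbind(map, data.frame(domain = "social_connections",
                                 code_stem = "Z60", stringsAsFactors = FALSE))
  }
  map
}

#' Per-domain SDOH flags from a patient's diagnosis records
#'
#' @param records data frame of one patient's diagnoses with a `code` column
#'   (normalized or raw; raw codes are normalized first).
#' @param code_map data frame from [sdoh_code_map()].
#' @return named logical vector over the map's domains.
#' @export
classify_patient_structured <- function(records, code_map = sdoh_code_map()) {
  domains <- unique(code_map$domain)
  flags <- setNames(rep(FALSE, length(domains)), domains)
  if (nrow(records) == 0L) return(flags)
  codes <- normalize_code(as.character(records$code))
  for (i in seq_len(nrow(code_map))) {
    d <- code_map$domain[i]
    if (!flags[[d]] && any(code_matches_stem(codes, code_map$code_stem[i]))) {
      flags[[d]] <- TRUE
    }
  }
  flags
}

#' Cohort-level structured SDOH flags
#'
#' @param diagnoses data frame with `patient_id`, `code`.
#' @param patients character vector of all cohort patient ids; defaults to
#'   the patients appearing in `diagnoses`.
#' @inheritParams classify_patient_structured
#' @return data frame with `patient_id` and one logical column per domain.
#' @export
structured_sdoh_flags <- function(diagnoses, patients = NULL,
                                  code_map = sdoh_code_map()) {
  if (is.null(patients)) patients <- sort(unique(diagnoses$patient_id))
  codes <- normalize_code(as.character(diagnoses$code))
  flags <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (d in unique(code_map$domain)) {
    stems <- code_map$code_stem[code_map$domain == d]
    hit <- Reduce(`|`, lapply(stems, function(s) code_matches_stem(codes, s)))
    hit_pat <- unique(diagnoses$patient_id[hit])
    flags[[d]] <- flags$patient_id %in% hit_pat
  }
  flags
}

#' Select the primary-care diabetes cohort
#'
#' A patient is included iff, within the study window, they (a) completed at
#' least two primary-care encounters on distinct dates, and (b) have at
#' least one diabetes diagnosis (E10 or E11 or any child code). When an
#' `ages` table is supplied, patients under `min_age` are excluded;
#' otherwise all patients are treated as adults (and a message notes it).
#'
#' @param encounters data frame: `patient_id`, `department_class` (one of
#'   "primary care", "specialty", "other"), `date`, `completed` (logical).
#' @param diagnoses data frame: `patient_id`, `code`, `date`.
#' @param window length-2 `Date` vector, closed interval.
#' @param ages optional data frame: `patient_id`, `age`.
#' @param min_age adult threshold in years.
#' @return sorted character vector of included patient ids.
#' @export
select_diabetes_cohort <- function(encounters, diagnoses,
                                   window = as.Date(c("2018-01-01", "2019-12-31")),
                                   ages = NULL, min_age = 18) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  enc <- encounters[encounters$department_class == "primary care" &
                      as.logical(encounters$completed) &
                      as.Date(encounters$date) >= window[1] &
                      as.Date(encounters$date) <= window[2], , drop = FALSE]
  n_dates <- tapply(as.character(enc$date), enc$patient_id,
                    function(d) length(unique(d)))
  visits_ok <- names(n_dates)[n_dates >= 2L]
  codes <- normalize_code(as.character(diagnoses$code))
  dm <- code_matches_stem(codes, "E10") | code_matches_stem(codes, "E11")
  dm <- dm & as.Date(diagnoses$date) >= window[1] &
    as.Date(diagnoses$date) <= window[2]
  dx_ok <- unique(diagnoses$patient_id[dm])
  cohort <- intersect(visits_ok, dx_ok)
  if (!is.null(ages)) {
    adult <- ages$patient_id[ages$age >= min_age]
    cohort <- intersect(cohort, adult)
  } else {
    message("no age data supplied; treating all patients as adults")
  }
  sort(cohort)
}

#' Read diagnosis records from CSV (`patient_id`, `code`, `date`)
#' @param path file path.
#' @return data frame with `date` parsed to `Date`.
#' @export
read_diagnoses_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character", code = "character"))
  x$date <- as.Date(x$date)
  x
}

#' Read encounter records from CSV
#' (`patient_id`, `department_class`, `date`, `completed`)
#' @param path file path.
#' @return data frame with `date` parsed to `Date`, `completed` logical.
#' @export
read_encounters_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  x$date <- as.Date(x$date)
  x$completed <- as.logical(x$completed)
  x
}
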