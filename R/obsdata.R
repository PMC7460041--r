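#' Focal-sampling observation datasets
#'
#' An `obs_dataset` bundles one collection period of focal-sampling data:
#' an individuals table (ID, sex, birth date), per-focal metadata, per-minute
#' nearest-neighbour scans (a scan may record several equidistant
#' neighbours), and timed dyadic interaction events classified as affiliative
#' or aggressive with directionality (actor vs receiver) preserved.
#'
#' @param individuals data.frame with columns `id` (unique short codes),
#'   `sex` (`"female"`/`"male"`), `birth_date` (`Date` or ISO-8601 string).
#' @param focals data.frame with columns `focal_id`, `date`, `duration_s`.
#' @param scans data.frame with columns `focal_id`, `timestamp`,
#'   `neighbour_ids` (IDs separated by `";"` when equidistant neighbours
#'   were recorded in the same scan).
#' @param interactions data.frame with columns `focal_id`, `timestamp`,
#'   `actor_id`, `receiver_id`, `category` (`"affiliative"`/`"aggressive"`),
#'   `duration_s`.
#' @param period_label character label for the collection period.
#' @param scan_slack allowed absolute difference between a focal's scan count
#'   and its duration in minutes before a warning is issued; partial focals
#'   (e.g. terminated when the animal was lost) are retained with their
#'   actual duration.
#' @return A validated object of class `obs_dataset`.
#' @export
obs_dataset <- function(individuals, focals, scans, interactions,
                        period_label = "unlabelled", scan_slack = 2) {
  ds <- structure(
    list(period_label = as.character(period_label),
         individuals = as.data.frame(individuals),
         focals = as.data.frame(focals),
         scans = as.data.frame(scans),
         interactions = as.data.frame(interactions)),
    class = "obs_dataset")
  validate_dataset(ds, scan_slack = scan_slack)
}

required_cols <- list(
  individuals  = c("id", "sex", "birth_date"),
  focals       = c("focal_id", "date", "duration_s"),
  scans        = c("focal_id", "timestamp", "neighbour_ids"),
  interactions = c("focal_id", "timestamp", "actor_id", "receiver_id",
                   "category", "duration_s"))

#' Validate a focal-sampling dataset
#'
#' Checks the structural invariants of an [obs_dataset()]: required columns,
#' unique IDs, known sexes and categories, no unknown IDs in scans or
#' interactions, no duplicate focal of the same individual on the same
#' calendar day, no negative durations, focal never its own neighbour, and
#' actor distinct from receiver. Each violation raises a distinct condition
#' class (`focalsna_missing_column`, `focalsna_unknown_id`,
#' `focalsna_duplicate_focal`, `focalsna_negative_duration`,
#' `focalsna_invalid_value`).
#'
#' @param ds an `obs_dataset` (or a bare list with the same components).
#' @param scan_slack see [obs_dataset()].
#' @return `ds`, invisibly classed as `obs_dataset`.
#' @export
validate_dataset <- function(ds, scan_slack = 2) {
  for (tbl in names(required_cols)) {
    missing <- setdiff(required_cols[[tbl]], names(ds[[tbl]]))
    if (length(missing))
      fsna_stop(sprintf("table '%s' is missing column(s): %s",
                        tbl, paste(missing, collapse = ", ")),
                "focalsna_missing_column")
  }
  ind <- ds$individuals
  if (anyDuplicated(ind$id))
    fsna_stop("duplicate individual id(s) in individuals table",
              "focalsna_invalid_value")
  if (!all(ind$sex %in% c("female", "male")))
    fsna_stop("sex must be 'female' or 'male'", "focalsna_invalid_value")
  ds$individuals$birth_date <- as.Date(ind$birth_date)
  ds$focals$date <- as.Date(ds$focals$date)
  ids <- ind$id

  check_ids <- function(x, what) {
    bad <- which(!(x %in% ids))
    if (length(bad))
      fsna_stop(sprintf("unknown individual id '%s' in %s (row %d)",
                        x[bad[1]], what, bad[1]),
                "focalsna_unknown_id")
  }
  check_ids(ds$focals$focal_id, "focals")
  check_ids(ds$scans$focal_id, "scans")
  nb <- neighbour_sets(ds)
  check_ids(unlist(nb), "scan neighbour sets")
  check_ids(ds$interactions$focal_id, "interactions")
  check_ids(ds$interactions$actor_id, "interactions")
  check_ids(ds$interactions$receiver_id, "interactions")

  dup <- duplicated(ds$focals[c("focal_id", "date")])
  if (any(dup))
    fsna_stop(sprintf(
      "individual '%s' has more than one focal on %s",
      ds$focals$focal_id[which(dup)[1]],
      format(ds$focals$date[which(dup)[1]])),
      "focalsna_duplicate_focal")

  if (any(ds$focals$duration_s <= 0))
    fsna_stop("focal duration_s must be positive",
              "focalsna_negative_duration")
  if (nrow(ds$interactions) && any(ds$interactions$duration_s < 0))
    fsna_stop("interaction duration_s must be non-negative",
              "focalsna_negative_duration")
  if (nrow(ds$interactions)) {
    if (!all(ds$interactions$category %in% c("affiliative", "aggressive")))
      fsna_stop("interaction category must be 'affiliative' or 'aggressive'",
                "focalsna_invalid_value")
    if (any(ds$interactions$actor_id == ds$interactions$receiver_id))
      fsna_stop("actor_id must differ from receiver_id",
                "focalsna_invalid_value")
  }
  if (nrow(ds$scans)) {
    self_nb <- mapply(function(f, s) f %in% s, ds$scans$focal_id, nb)
    if (any(self_nb))
      fsna_stop(sprintf("focal '%s' recorded as its own neighbour",
                        ds$scans$focal_id[which(self_nb)[1]]),
                "focalsna_invalid_value")
    if (any(lengths(nb) == 0))
      fsna_stop("empty neighbour set in scans", "focalsna_invalid_value")
  }

  # scans-per-focal ~ duration in minutes, within tolerance
  if (nrow(ds$focals)) {
    key <- paste(ds$focals$focal_id, ds$focals$date)
    sc_key <- paste(ds$scans$focal_id, as.Date(ds$scans$timestamp))
    n_scans <- as.numeric(table(factor(sc_key, levels = key)))
    exp_scans <- ds$focals$duration_s / 60
    off <- abs(n_scans - exp_scans) > scan_slack
    if (any(off))
      warning(sprintf(
        "%d focal(s) have a scan count differing from duration (min) by more than %g",
        sum(off), scan_slack), call. = FALSE)
  }
  class(ds) <- "obs_dataset"
  ds
}

# Parse the ";"-separated neighbour cells into a list of character vectors.
neighbour_sets <- function(ds) {
  if (!nrow(ds$scans)) return(list())
  lapply(strsplit(as.character(ds$scans$neighbour_ids), ";", fixed = TRUE),
         function(x) unique(trimws(x[nzchar(trimws(x))])))
}

#' Read a focal-sampling dataset from delimited text files
#'
#' Expects four UTF-8 comma-delimited files: `individuals.csv`
#' (`id,sex,birth_date`), `focals.csv` (`focal_id,date,duration_s`),
#' `scans.csv` (`focal_id,timestamp,neighbour_ids`, neighbour IDs separated
#' by `";"` within the cell), `interactions.csv`
#' (`focal_id,timestamp,actor_id,receiver_id,category,duration_s`).
#' Dates are ISO-8601. Extra columns (e.g. an enclosure-section code on
#' scans) are carried through but unused by analysis.
#'
#' @param individuals_path,focals_path,scans_path,interactions_path file
#'   paths to the four tables.
#' @param period_label label for the collection period.
#' @param scan_slack see [obs_dataset()].
#' @return an [obs_dataset()].
#' @export
read_dataset <- function(individuals_path, focals_path, scans_path,
                         interactions_path, period_label = "unlabelled",
                         scan_slack = 2) {
  rd <- function(path) utils::read.csv(path, stringsAsFactors = FALSE,
                                       colClasses = "character")
  ind <- rd(individuals_path)
  foc <- rd(focals_path)
  sca <- rd(scans_path)
  int <- rd(interactions_path)
  if ("duration_s" %in% names(foc)) foc$duration_s <- as.numeric(foc$duration_s)
  if ("duration_s" %in% names(int)) int$duration_s <- as.numeric(int$duration_s)
  obs_dataset(ind, foc, sca, int, period_label = period_label,
              scan_slack = scan_slack)
}

#' Write a focal-sampling dataset to delimited text files
#'
#' Inverse of [read_dataset()]; the four CSV files round-trip field for
#' field.
#'
#' @param ds an [obs_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df <- as.data.frame(lapply(df, as.character))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(ds$individuals, "individuals.csv")
  wr(ds$focals, "focals.csv")
  wr(ds$scans, "scans.csv")
  wr(ds$interactions, "interactions.csv")
  invisible(dir)
}

#' @export
print.obs_dataset <- function(x, ...) {
  cat(sprintf(
    "Focal-sampling dataset '%s': %d individuals, %d focals, %d scans, %d interaction events\n",
    x$period_label, nrow(x$individuals), nrow(x$focals), nrow(x$scans),
    nrow(x$interactions)))
  invisible(x)
}

#' Per-individual observation effort
#'
#' Totals focal observation time per individual and summarises effort
#' (mean and sample standard deviation of total minutes) across the
#' individuals that received at least one focal.
#'
#' @param ds an [obs_dataset()].
#' @return a list of class `effort_summary` with `per_individual` (data.frame
#'   `id`, `n_focals`, `total_min`), `mean_min`, `sd_min`.
#' @export
summarize_effort <- function(ds) {
  ids <- ds$individuals$id
  fid <- factor(ds$focals$focal_id, levels = ids)
  total_s <- tapply(ds$focals$duration_s, fid, sum, default = 0)
  per <- data.frame(id = ids,
                    n_focals = as.integer(table(fid)),
                    total_min = as.numeric(total_s) / 60,
                    stringsAsFactors = FALSE)
  obs <- per$total_min[per$n_focals > 0]
  structure(list(per_individual = per,
                 mean_min = mean(obs),
                 sd_min = if (length(obs) > 1) stats::sd(obs) else 0),
            class = "effort_summary")
}

#' @export
print.effort_summary <- function(x, ...) {
  cat(sprintf(
    "Observation effort: %d sampled individuals, mean %.2f min (SD %.3f)\n",
    sum(x$per_individual$n_focals > 0), x$mean_min, x$sd_min))
  invisible(x)
}

#' Age in years at a reference date
#'
#' Real-valued age computed as elapsed days / 365.25; vectorised over both
#' arguments.
#'
#' @param birth_date `Date` (or coercible) birth date(s).
#' @param reference_date `Date` (or coercible) reference date(s).
#' @return numeric age(s) in years.
#' @export
age_at <- function(birth_date, reference_date) {
  b <- as.Date(birth_date)
  r <- as.Date(reference_date)
  if (any(r < b))
    fsna_stop("reference_date precedes birth_date", "focalsna_invalid_value")
  as.numeric(r - b) / 365.25
}
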