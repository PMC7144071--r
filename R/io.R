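#' Read a melt-curve export
#'
#' Reads the melt ramp exported by a real-time PCR instrument into a list of
#' [melt_curve()] objects. Two dialects are supported: the canonical long
#' format with columns `well`, `temperature`, `rfu` (one row per reading),
#' and a wide format with a `temperature` column and one column of RFU
#' readings per well. Proprietary binary instrument files are out of scope;
#' export to CSV first.
#'
#' Column matching is case-insensitive and tolerates the common header
#' variants `Temperature`/`temp` and `RFU`/`fluorescence`. Rows may appear
#' in any order; each well's readings are sorted by ascending temperature.
#' A repeated temperature within one well is rejected as a data error.
#'
#' @param path Path to the CSV export.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return Named list of raw `melt_curve` objects (names are well ids).
#' @export
read_melt_export <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("melt export not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "long") {
    wcol <- match_column(df, c("well"), path)
    tcol <- match_column(df, c("temperature", "temp"), path)
    rcol <- match_column(df, c("rfu", "fluorescence"), path)
    long <- data.frame(well = as.character(df[[wcol]]),
                       temperature = as.numeric(df[[tcol]]),
                       rfu = as.numeric(df[[rcol]]),
                       stringsAsFactors = FALSE)
  } else {
    tcol <- match_column(df, c("temperature", "temp"), path)
    wells <- setdiff(names(df), tcol)
    if (length(wells) == 0L)
      stop("wide melt export ", path, " has no well columns")
    long <- do.call(rbind, lapply(wells, function(w)
      data.frame(well = w, temperature = as.numeric(df[[tcol]]),
                 rfu = as.numeric(df[[w]]), stringsAsFactors = FALSE)))
  }
  if (anyNA(long$temperature))
    stop("non-numeric temperatures in ", path)
  curves <- lapply(split(long, long$well), function(g) {
    g <- g[order(g$temperature), , drop = FALSE]
    if (anyDuplicated(g$temperature))
      stop("well ", g$well[1L], " has repeated temperature readings in ",
           path, "; duplicated ramp points are a data error")
    melt_curve(g$well[1L], g$temperature, g$rfu)
  })
  curves[order(names(curves))]
}

match_column <- function(df, candidates, path) {
  hit <- which(tolower(names(df)) %in% candidates)
  if (length(hit) == 0L)
    stop("melt export ", path, " is missing a '", candidates[1L],
         "' column (found: ", paste(names(df), collapse = ", "), ")")
  names(df)[hit[1L]]
}

#' Construct a plate layout
#'
#' Maps the wells of one plate to their roles: `standard` wells with a known
#' marked-allele proportion, `unknown` sample wells, pure-allele positive
#' controls (`positive_marked`, `positive_wt`) and no-template controls
#' (`ntc`).
#'
#' @param wells A data frame with columns `well`, `role`, `known_proportion`
#'   and `sample_id` (the latter two may be `NA` where not applicable).
#' @param plate_id Plate identifier.
#' @param proportion_unit How `known_proportion` is scaled: `"fraction"`
#'   (values in `[0, 1]`), `"percent"` (values in `[0, 100]`, divided by 100
#'   on read), or `"auto"` (default): a column whose maximum exceeds 10 is
#'   taken as percent; values between 1 and 10 are rejected as ambiguous.
#' @return A validated data frame of class `plate_layout` with attribute
#'   `plate_id`. Proportions are fractions in `[0, 1]`.
#' @export
plate_layout <- function(wells, plate_id = "plate1",
                         proportion_unit = c("auto", "fraction", "percent")) {
  proportion_unit <- match.arg(proportion_unit)
  req <- c("well", "role", "known_proportion", "sample_id")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("layout is missing columns: ", paste(miss, collapse = ", "))
  wells <- as.data.frame(wells)[req]
  wells$well <- as.character(wells$well)
  wells$role <- as.character(wells$role)
  wells$sample_id <- as.character(wells$sample_id)
  wells$sample_id[!nzchar(wells$sample_id) | is.na(wells$sample_id)] <- NA_character_
  wells$known_proportion <- as.numeric(wells$known_proportion)
  roles <- c("standard", "unknown", "positive_marked", "positive_wt", "ntc")
  bad <- setdiff(unique(wells$role), roles)
  if (length(bad))
    stop("unknown well role(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(roles, collapse = ", "), ")")
  if (anyDuplicated(wells$well))
    stop("duplicated well id(s) in layout: ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  is_std <- wells$role == "standard"
  if (any(is_std & is.na(wells$known_proportion)))
    stop("standard wells must have a known_proportion")
  if (any(!is_std & !is.na(wells$known_proportion)))
    stop("known_proportion is only allowed on standard wells")
  # percent inputs are converted at this boundary
  kp <- wells$known_proportion[is_std]
  as_percent <- proportion_unit == "percent" ||
    (proportion_unit == "auto" && length(kp) && max(kp) > 10)
  if (as_percent) {
    if (length(kp) && (max(kp) > 100 || min(kp) < 0))
      stop("percent known_proportion outside [0, 100]")
    wells$known_proportion[is_std] <- kp / 100
  }
  kp <- wells$known_proportion[is_std]
  if (length(kp) && (min(kp) < 0 || max(kp) > 1))
    stop("known_proportion must lie in [0, 1]")
  is_unk <- wells$role == "unknown"
  if (any(is_unk & is.na(wells$sample_id)))
    stop("unknown wells must carry a sample_id")
  if (any(!is_unk & !is.na(wells$sample_id)))
    stop("sample_id is only allowed on unknown wells")
  structure(wells, class = c("plate_layout", "data.frame"),
            plate_id = as.character(plate_id))
}

#' Read a plate layout CSV
#'
#' @param path CSV with columns `well`, `role`, `known_proportion`,
#'   `sample_id`. `known_proportion` may be given as fractions or percent
#'   (detected from the column maximum).
#' @param plate_id Plate identifier; defaults to the file name.
#' @param proportion_unit See [plate_layout()].
#' @return A [plate_layout()].
#' @export
read_layout <- function(path, plate_id = NULL,
                        proportion_unit = c("auto", "fraction", "percent")) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_layout(df, plate_id = plate_id %||% sub("\\.csv$", "", basename(path)),
               proportion_unit = match.arg(proportion_unit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a competition design table
#'
#' One row per assayed sample: which population and competition it belongs
#' to, the transfer number at which it was taken, and the genotype coding of
#' the two competing strains. `marked_strain_matA` is the mating-type
#' indicator m (+1 when the marked strain is *mat A*, -1 when it is
#' *mat a*, 0 when both competitors share a mating type);
#' `focal_in_marked` is the indicator c (+1 when the focal-mutation strain
#' carries the marked allele, -1 otherwise) and may be absent for designs
#' without a focal mutation.
#'
#' @param path CSV with columns `sample_id`, `population_id`,
#'   `competition_id`, `transfer`, `marked_strain_matA` and optionally
#'   `focal_in_marked`.
#' @return A validated data frame of class `competition_design`.
#' @export
read_competition_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  competition_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_competition_design
#' @param records Data frame of design records (see `read_competition_design`).
#' @export
competition_design <- function(records) {
  req <- c("sample_id", "population_id", "competition_id", "transfer",
           "marked_strain_matA")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(records)
  if (!"focal_in_marked" %in% names(d)) d$focal_in_marked <- NA_integer_
  d <- d[c(req, "focal_in_marked")]
  d$sample_id <- as.character(d$sample_id)
  d$population_id <- as.character(d$population_id)
  d$competition_id <- as.character(d$competition_id)
  d$transfer <- as.integer(d$transfer)
  if (anyNA(d$transfer) || any(d$transfer < 0L))
    stop("transfer must be a non-negative integer")
  if (!all(d$marked_strain_matA %in% c(-1L, 0L, 1L)))
    stop("marked_strain_matA must be -1, 0 or +1")
  ok_c <- is.na(d$focal_in_marked) | d$focal_in_marked %in% c(-1L, 1L)
  if (!all(ok_c)) stop("focal_in_marked must be -1 or +1 when present")
  key <- paste(d$population_id, d$transfer)
  if (anyDuplicated(key))
    stop("duplicated (population, transfer) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id(s) in design")
  structure(d, class = c("competition_design", "data.frame"))
}

#' Write and read proportion-estimate tables
#'
#' `write_proportions()` stores the posterior summaries of a set of
#' [estimate_proportion()] results as CSV (columns `sample_id`, `mean`,
#' `sd`, `hpdi_lower`, `hpdi_upper`, `n_draws`); `read_proportions()` reads
#' the table back for the fitness stage. Summaries round-trip to at least
#' six decimals.
#'
#' @param estimates A `proportion_estimates` object (or a data frame with
#'   the columns above).
#' @param path Output/input CSV path.
#' @return `write_proportions()` returns `path` invisibly;
#'   `read_proportions()` returns the summary data frame.
#' @export
write_proportions <- function(estimates, path) {
  df <- as.data.frame(estimates)
  if (nrow(df) == 0L) stop("no proportion estimates to write")
  req <- c("sample_id", "mean", "sd", "hpdi_lower", "hpdi_upper", "n_draws")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("estimates are missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(df[req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("proportions file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "mean", "sd", "hpdi_lower", "hpdi_upper", "n_draws")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("proportions file is missing columns: ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Match exported curves to a plate layout
#'
#' Pairs each well named in the layout with its curve from the melt export.
#' Layout wells missing from the export are reported in a warning (never
#' silently dropped); exported wells absent from the layout are ignored.
#'
#' @param curves Named list of `melt_curve` objects (from
#'   [read_melt_export()] or [simulate_melt_plate()]).
#' @param layout A [plate_layout()].
#' @return The layout with a list-column-free pairing: a list with elements
#'   `curves` (matched, in layout order) and `layout` (rows with a curve).
#' @keywords internal
match_wells <- function(curves, layout) {
  nm <- names(curves)
  present <- layout$well %in% nm
  if (any(!present))
    warning("layout well(s) missing from the melt export: ",
            paste(layout$well[!present], collapse = ", "))
  list(curves = curves[layout$well[present]],
       layout = layout[present, , drop = FALSE])
}
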