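#' Build a species response record
#'
#' One respondent's identification and sighting outcome for one focal species.
#' For leopard and wolf the photo is shown alongside a look-alike (tiger and
#' jackal); `paired_set_correct` records whether each look-alike was correctly
#' told apart. Species without a paired set carry an empty vector, which is
#' vacuously correct.
#'
#' @param species one of [FOCAL_SPECIES].
#' @param paired_set_correct logical vector (length 0 or 1 here; the protocol
#'   pairs at most one look-alike per species).
#' @param hint_used did the respondent need a hint to identify the focal
#'   species?
#' @param focal_identified was the focal species identified (with or without
#'   hint)?
#' @param sighting_reported,sighting_in_focal_grid,sighting_within_past_year
#'   sighting validity flags; all must be FALSE when no sighting is reported.
#' @param sighting_notes free text, ignored by the classifier.
#' @return a `speciesResponse` list.
#' @export
speciesResponse <- function(species,
                            paired_set_correct = logical(),
                            hint_used = FALSE,
                            focal_identified = TRUE,
                            sighting_reported = FALSE,
                            sighting_in_focal_grid = FALSE,
                            sighting_within_past_year = FALSE,
                            sighting_notes = "") {
  species <- match.arg(species, FOCAL_SPECIES)
  if (!sighting_reported &&
      (sighting_in_focal_grid || sighting_within_past_year))
    stop("inconsistent flags: sighting details present without a reported sighting")
  structure(list(
    species = species,
    paired_set_correct = as.logical(paired_set_correct),
    hint_used = isTRUE(hint_used),
    focal_identified = isTRUE(focal_identified),
    sighting_reported = isTRUE(sighting_reported),
    sighting_in_focal_grid = isTRUE(sighting_in_focal_grid),
    sighting_within_past_year = isTRUE(sighting_within_past_year),
    sighting_notes = as.character(sighting_notes)
  ), class = "speciesResponse")
}

#' Classify one response into a detection state
#'
#' Implements the identification flowchart. A detection is CERTAIN (state 2)
#' only if every look-alike of the paired set and the focal species were
#' identified without any hint AND the sighting is valid (reported, inside the
#' focal grid, within the past year). A valid sighting with identification
#' that needed a hint or stumbled on a look-alike is UNCERTAIN (state 1).
#' Failing to identify the focal species even with a hint voids the replicate
#' for that species (`"FAILED"`). Anything without a valid sighting — none
#' reported, on or outside the grid border, or older than a year — is a
#' non-detection (state 0); border sightings are deliberately conservative.
#'
#' @param resp a [speciesResponse()].
#' @return `"0"`, `"1"`, `"2"` or `"FAILED"`.
#' @examples
#' classifyDetection(speciesResponse("hyena",
#'   sighting_reported = TRUE, sighting_in_focal_grid = TRUE,
#'   sighting_within_past_year = TRUE))  # "2"
#' @export
classifyDetection <- function(resp) {
  stopifnot(inherits(resp, "speciesResponse"))
  if (!resp$focal_identified) return("FAILED")
  valid <- resp$sighting_reported && resp$sighting_in_focal_grid &&
    resp$sighting_within_past_year
  if (!valid) return("0")
  certain <- all(resp$paired_set_correct) && !resp$hint_used
  if (certain) "2" else "1"
}

#' Replicate validity from sub-grid coverage
#'
#' A focal grid is split into four sub-grids. A respondent covering at least
#' three is an independent replicate; one covering exactly two must be paired
#' with a complementary respondent; fewer than two means no interview is
#' conducted.
#'
#' @param subgrids integer vector, subset of `1:4`.
#' @return `"independent"`, `"needs_pairing"` or `"invalid"`.
#' @export
validateReplicate <- function(subgrids) {
  subgrids <- unique(as.integer(subgrids))
  stopifnot(all(subgrids %in% 1:4))
  n <- length(subgrids)
  if (n >= 3) "independent" else if (n == 2) "needs_pairing" else "invalid"
}

#' Build an interview record
#'
#' @param respondent_id identifier.
#' @param focal_grid_id grid-cell identifier.
#' @param subgrids_covered subset of `1:4`, at least two (interviews with
#'   fewer are never conducted).
#' @param years_experience non-negative; midpoint when reported as a range.
#' @param merged_pair was this entry formed from two respondents?
#' @param responses named list of [speciesResponse()], one per focal species
#'   present in the interview.
#' @return an `interviewRecord` list.
#' @export
interviewRecord <- function(respondent_id, focal_grid_id, subgrids_covered,
                            years_experience, merged_pair = FALSE,
                            responses = list()) {
  subgrids_covered <- sort(unique(as.integer(subgrids_covered)))
  if (length(subgrids_covered) < 2)
    stop("interview covers fewer than two sub-grids")
  if (years_experience < 0) stop("years_experience must be non-negative")
  structure(list(
    respondent_id = as.character(respondent_id),
    focal_grid_id = as.character(focal_grid_id),
    subgrids_covered = subgrids_covered,
    years_experience = as.numeric(years_experience),
    merged_pair = isTRUE(merged_pair),
    responses = responses
  ), class = "interviewRecord")
}

# combine two classified states for one species under the merged-pair rule:
# a failed identification by either respondent voids the replicate; otherwise
# the more certain state wins.
combineStates <- function(s1, s2) {
  if (s1 == "FAILED" || s2 == "FAILED") return("FAILED")
  as.character(max(as.integer(s1), as.integer(s2)))
}

#' Merge two two-sub-grid interviews into a single replicate
#'
#' Respondents covering only two sub-grids each are combined into one entry
#' when their joint coverage reaches at least three sub-grids. The merged
#' entry keeps the longer herding experience; per species, the merged state is
#' FAILED if either respondent failed identification, otherwise the maximum
#' of the two states.
#'
#' @param a,b [interviewRecord()]s for the same focal grid.
#' @return a merged `interviewRecord` with `merged_pair = TRUE`.
#' @export
mergePaired <- function(a, b) {
  stopifnot(inherits(a, "interviewRecord"), inherits(b, "interviewRecord"))
  if (a$focal_grid_id != b$focal_grid_id)
    stop("cannot merge interviews from different focal grids")
  subs <- sort(union(a$subgrids_covered, b$subgrids_covered))
  if (length(subs) < 3)
    stop("merged coverage still below three sub-grids")
  sp <- union(names(a$responses), names(b$responses))
  merged <- lapply(sp, function(s) {
    ra <- a$responses[[s]]; rb <- b$responses[[s]]
    if (is.null(ra)) return(rb)
    if (is.null(rb)) return(ra)
    sa <- classifyDetection(ra); sb <- classifyDetection(rb)
    st <- combineStates(sa, sb)
    # keep the response whose classification equals the merged state so the
    # merged record re-classifies to it; FAILED needs a failed-ID response
    if (st == "FAILED") {
      if (sa == "FAILED") ra else rb
    } else if (st == sa) ra else rb
  })
  names(merged) <- sp
  interviewRecord(
    respondent_id = paste(a$respondent_id, b$respondent_id, sep = "+"),
    focal_grid_id = a$focal_grid_id,
    subgrids_covered = subs,
    years_experience = max(a$years_experience, b$years_experience),
    merged_pair = TRUE,
    responses = merged
  )
}

#' Assemble the detection matrix for one species
#'
#' Orders interviews by ingestion sequence within each site, classifies each
#' response, turns FAILED outcomes into missing replicates for that species
#' only, and attaches per-replicate detection covariates (`grid_covered` = 1
#' iff all four sub-grids were covered, and `years_experience`). Sites whose
#' every replicate failed identification for the species are dropped with a
#' warning — this is why per-species site counts differ.
#'
#' @param records list of validated/merged [interviewRecord()]s.
#' @param species one of [FOCAL_SPECIES].
#' @return a [DetectionMatrix-class].
#' @export
buildDetectionMatrix <- function(records, species) {
  species <- match.arg(species, FOCAL_SPECIES)
  keys <- vapply(records, function(r)
    paste(r$focal_grid_id, r$respondent_id), "")
  if (anyDuplicated(keys))
    stop("duplicate (site, respondent) keys in interview set")
  grid <- vapply(records, function(r) r$focal_grid_id, "")
  sites <- unique(grid)
  rows <- lapply(sites, function(g) {
    recs <- records[grid == g]
    st <- vapply(recs, function(r) {
      resp <- r$responses[[species]]
      if (is.null(resp)) NA_character_ else classifyDetection(resp)
    }, "")
    list(
      states = match(st, c("0", "1", "2")) - 1L,  # FAILED / absent -> NA
      covered = vapply(recs, function(r)
        as.numeric(length(r$subgrids_covered) == 4L), 0),
      exper = vapply(recs, function(r) r$years_experience, 0)
    )
  })
  usable <- vapply(rows, function(r) any(!is.na(r$states)), TRUE)
  if (any(!usable)) {
    warning(sprintf("dropping %d site(s) with no usable replicate for %s: %s",
                    sum(!usable), species,
                    paste(sites[!usable], collapse = ", ")))
    rows <- rows[usable]; sites <- sites[usable]
  }
  if (!length(rows)) stop("no sites with usable replicates for ", species)
  # compact each row: usable replicates keep interview order, pad with NA
  maxrep <- max(vapply(rows, function(r) sum(!is.na(r$states)), 0L))
  pad <- function(x, fill = NA_real_) c(x, rep(fill, maxrep - length(x)))
  st <- t(vapply(rows, function(r) {
    keep <- !is.na(r$states)
    pad(as.numeric(r$states[keep]))
  }, numeric(maxrep)))
  cov_cover <- t(vapply(rows, function(r)
    pad(r$covered[!is.na(r$states)]), numeric(maxrep)))
  cov_exp <- t(vapply(rows, function(r)
    pad(r$exper[!is.na(r$states)]), numeric(maxrep)))
  st <- matrix(as.integer(st), nrow(st), ncol(st))
  bin <- ifelse(is.na(st), NA_integer_, ifelse(st == 2L, 1L, 0L))
  rownames(st) <- rownames(bin) <- sites
  new("DetectionMatrix", species = species, states = st, binary = bin,
      siteIDs = sites,
      detCovariates = list(grid_covered = cov_cover,
                           years_experience = cov_exp))
}

#' Read an interview file
#'
#' Comma-separated, one row per respondent-per-grid. Base columns:
#' `respondent_id`, `focal_grid_id`, `subgrids_covered` (e.g. `"1;2;3"`),
#' `years_experience`, `merged_pair`. Per species `<sp>` in
#' [FOCAL_SPECIES], six flag columns: `<sp>_paired_correct` (NA for species
#' without a paired set), `<sp>_hint_used`, `<sp>_focal_identified`,
#' `<sp>_sighting_reported`, `<sp>_sighting_in_grid`, `<sp>_sighting_past_year`.
#'
#' @param path file path.
#' @return list of [interviewRecord()]s.
#' @export
readInterviews <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  base <- c("respondent_id", "focal_grid_id", "subgrids_covered",
            "years_experience", "merged_pair")
  miss <- setdiff(base, names(df))
  if (length(miss))
    stop("interview file missing columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    responses <- list()
    for (sp in FOCAL_SPECIES) {
      cols <- paste0(sp, c("_paired_correct", "_hint_used",
                           "_focal_identified", "_sighting_reported",
                           "_sighting_in_grid", "_sighting_past_year"))
      if (!all(cols %in% names(df))) next
      pc <- row[[cols[1]]]
      responses[[sp]] <- speciesResponse(
        species = sp,
        paired_set_correct = if (is.na(pc)) logical() else as.logical(pc),
        hint_used = as.logical(row[[cols[2]]]),
        focal_identified = as.logical(row[[cols[3]]]),
        sighting_reported = as.logical(row[[cols[4]]]),
        sighting_in_focal_grid = as.logical(row[[cols[5]]]),
        sighting_within_past_year = as.logical(row[[cols[6]]])
      )
    }
    interviewRecord(
      respondent_id = row$respondent_id,
      focal_grid_id = row$focal_grid_id,
      subgrids_covered = as.integer(strsplit(
        as.character(row$subgrids_covered), ";")[[1]]),
      years_experience = row$years_experience,
      merged_pair = as.logical(row$merged_pair),
      responses = responses
    )
  })
}

#' Write a detection history to delimited text
#'
#' Exports both layers: `state_1..state_J` over `{0,1,2,NA}` and
#' `det_1..det_J` over `{0,1,NA}`, keyed by `site_id`.
#'
#' @param dm a [DetectionMatrix-class].
#' @param path output file.
#' @export
writeDetectionHistory <- function(dm, path) {
  st <- detectionStates(dm)
  bn <- detectionBinary(dm)
  colnames(st) <- paste0("state_", seq_len(ncol(st)))
  colnames(bn) <- paste0("det_", seq_len(ncol(bn)))
  out <- data.frame(site_id = siteIDs(dm), st, bn, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Z-score replicate-level detection covariates
#'
#' Standardizes each detection-covariate matrix over its observed cells with
#' the sample standard deviation, leaving binary indicators (values in
#' `{0, 1}`) untouched so `grid_covered` keeps its coding. Covariates on a
#' common scale keep the logit-linear detection model numerically
#' well-conditioned.
#'
#' @param dm a [DetectionMatrix-class].
#' @return the matrix with standardized covariate slots.
#' @export
standardizeDetCovariates <- function(dm) {
  dcv <- detectionCovariates(dm)
  for (nm in names(dcv)) {
    m <- dcv[[nm]]
    vals <- m[!is.na(detectionStates(dm))]
    if (all(vals %in% c(0, 1))) next
    s <- sd(vals)
    if (!is.finite(s) || s == 0) next
    dcv[[nm]] <- (m - mean(vals)) / s
  }
  dm@detCovariates <- dcv
  dm
}

#' Per-site summary with replicate counts and naive occupancy
#'
#' @param dm a [DetectionMatrix-class].
#' @return data.frame with `site_id`, `n_replicates`, `n_detections`,
#'   `detected`; the naive occupancy (2 decimals) is attached as attribute
#'   `naive_occupancy`.
#' @export
siteSummary <- function(dm) {
  bn <- detectionBinary(dm)
  out <- data.frame(
    site_id = siteIDs(dm),
    n_replicates = rowSums(!is.na(bn)),
    n_detections = rowSums(bn == 1L, na.rm = TRUE)
  )
  out$detected <- out$n_detections > 0
  attr(out, "naive_occupancy") <- round(naiveOccupancy(dm), 2)
  out
}
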