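#' Read a community table from delimited text
#'
#' Reads a long-format table (one row per sample x taxon), validates each row,
#' and splits it into a deduplicated site table and a sample table. Rows with
#' non-numeric or negative abundance, or non-positive sampling area, are
#' rejected (not dropped silently): they are returned in the
#' \code{rejected} slot with a reason, so that rows read + rows rejected
#' equals rows in the file.
#'
#' @param path delimited text file (comma or tab, UTF-8, header row).
#' @param schema named character vector mapping the canonical column names
#'   (\code{site_id}, \code{sample_id}, \code{taxon}, \code{abundance},
#'   \code{sampling_area}, \code{sampling_depth}, \code{layers},
#'   \code{method}, \code{latitude}, \code{longitude}, \code{habitat},
#'   \code{soil_temperature}) to the file's column names. Defaults to
#'   identity.
#' @param quiet suppress the per-file summary message.
#' @return A [CommunityData-class] object.
#' @examples
#' f <- system.file("extdata", "community_example.csv",
#'                  package = "springtailMetrics")
#' cd <- readCommunityTable(f, quiet = TRUE)
#' nSites(cd)
#' @export
readCommunityTable <- function(path, schema = NULL, quiet = FALSE) {
  stopIfNot(file.exists(path), paste("file not found:", path))
  raw <- utils::read.delim(path, sep = guessDelim(path),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  canonical <- c(SAMPLE_COLUMNS, SITE_COLUMNS[-1])
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      stopIfNot(src %in% names(raw),
                paste0("schema maps '", canon, "' to missing column '", src, "'"))
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("site_id", "sample_id", "taxon", "abundance",
                 "sampling_area", "latitude", "longitude", "habitat")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)

  abundance <- suppressWarnings(as.numeric(raw$abundance))
  area <- suppressWarnings(as.numeric(raw$sampling_area))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(abundance)] <- "non-numeric abundance"
  reason[!is.na(abundance) & abundance < 0] <- "negative abundance"
  reason[is.na(reason) & (is.na(area) | area <= 0)] <-
    "missing or non-positive sampling_area"
  reason[is.na(reason) & (is.na(lat) | abs(lat) > 90)] <-
    "latitude missing or out of range"
  reason[is.na(reason) & (is.na(lon) | abs(lon) > 180)] <-
    "longitude missing or out of range"
  reason[is.na(reason) & !(raw$habitat %in% HABITAT_LEVELS)] <-
    "unknown habitat"
  keep <- is.na(reason)

  rejected <- cbind(data.frame(row = which(!keep)), raw[!keep, , drop = FALSE],
                    data.frame(reason = reason[!keep]))
  ok <- raw[keep, , drop = FALSE]
  samples <- data.frame(
    site_id = ok$site_id,
    sample_id = ok$sample_id,
    taxon = ok$taxon,
    abundance = abundance[keep],
    sampling_area = area[keep],
    sampling_depth = if ("sampling_depth" %in% names(ok))
      suppressWarnings(as.numeric(ok$sampling_depth)) else NA_real_,
    layers = if ("layers" %in% names(ok)) ok$layers else NA_character_,
    method = if ("method" %in% names(ok)) ok$method else "area_based",
    stringsAsFactors = FALSE)

  siteRows <- !duplicated(ok$site_id)
  sites <- data.frame(
    site_id = ok$site_id[siteRows],
    latitude = lat[keep][siteRows],
    longitude = lon[keep][siteRows],
    habitat = ok$habitat[siteRows],
    soil_temperature = if ("soil_temperature" %in% names(ok))
      suppressWarnings(as.numeric(ok$soil_temperature))[siteRows] else NA_real_,
    stringsAsFactors = FALSE)

  if (!quiet)
    message(sprintf("%s: %d rows read, %d samples kept, %d rejected, %d sites",
                    basename(path), nrow(raw), nrow(samples), nrow(rejected),
                    nrow(sites)))
  communityData(samples, sites, rejected)
}

#' Load the packaged genus checklist
#'
#' A plain-text list of accepted collembolan genus names used for offline
#' taxon-name harmonization.
#'
#' @return character vector of genus names.
#' @export
defaultChecklist <- function() {
  readLines(system.file("extdata", "genus_checklist.txt",
                        package = "springtailMetrics", mustWork = TRUE))
}

#' Harmonize a taxon name against a checklist
#'
#' Matches raw names against a checklist of accepted names by Levenshtein
#' edit distance (case-insensitive), correcting typographic variants. Ties
#' are broken by smallest distance, then alphabetically, so the result is
#' deterministic. Names farther than \code{max_distance} from every
#' checklist entry are returned unmatched.
#'
#' @param raw_name character vector of names to match.
#' @param checklist character vector of accepted names (non-empty).
#' @param max_distance maximum edit distance accepted for a fuzzy match
#'   (default 2).
#' @return data.frame with columns \code{raw_name}, \code{matched_name},
#'   \code{genus} (first whitespace-delimited token of the match),
#'   \code{match_distance} and \code{status}
#'   (\code{exact}/\code{fuzzy}/\code{unmatched}).
#' @examples
#' harmonizeTaxon(c("Folsomia", "Folsomai"), defaultChecklist())
#' @export
harmonizeTaxon <- function(raw_name, checklist = defaultChecklist(),
                           max_distance = 2L) {
  stopIfNot(length(checklist) > 0, "checklist must be non-empty")
  stopIfNot(max_distance >= 0, "max_distance must be >= 0")
  checklist <- sort(unique(checklist))
  out <- data.frame(raw_name = as.character(raw_name),
                    matched_name = NA_character_,
                    genus = NA_character_,
                    match_distance = NA_real_,
                    status = "unmatched",
                    stringsAsFactors = FALSE)
  nz <- nzchar(trimws(out$raw_name)) & !is.na(raw_name)
  if (any(nz)) {
    d <- utils::adist(tolower(trimws(out$raw_name[nz])), tolower(checklist))
    # checklist sorted alphabetically, so which.min's first-match rule is the
    # alphabetical tie-break
    best <- apply(d, 1L, which.min)
    bestDist <- d[cbind(seq_len(nrow(d)), best)]
    hit <- bestDist <= max_distance
    idx <- which(nz)[hit]
    out$matched_name[idx] <- checklist[best[hit]]
    out$genus[idx] <- vapply(strsplit(out$matched_name[idx], "\\s+"),
                             `[`, character(1), 1L)
    out$match_distance[idx] <- bestDist[hit]
    out$status[idx] <- ifelse(bestDist[hit] == 0, "exact", "fuzzy")
  }
  out
}

#' Classify latitude into climate bands
#'
#' Polar beyond the polar circles (|lat| > 66.5), tropical equatorward of the
#' tropics (|lat| <= 23.5), temperate in between. Boundaries are closed on
#' the equatorward side: exactly 66.5 is temperate, exactly 23.5 tropical.
#'
#' @param latitude numeric vector, degrees in [-90, 90].
#' @return factor with levels polar/temperate/tropical.
#' @examples
#' classifyClimateBand(c(70, 45, -10))
#' @export
classifyClimateBand <- function(latitude) {
  stopIfNot(all(is.finite(latitude)) && all(abs(latitude) <= 90),
            "latitude must be finite and within [-90, 90]")
  a <- abs(latitude)
  band <- ifelse(a > 66.5, "polar", ifelse(a > 23.5, "temperate", "tropical"))
  factor(band, levels = CLIMATE_BANDS)
}

#' Combine climate band and habitat into an ecosystem type
#'
#' @param climate_band character/factor of climate bands.
#' @param habitat character/factor of habitat classes.
#' @return data.frame with columns \code{ecosystem_type} (e.g.
#'   \code{"temperate_woodland"}) and \code{retained} (whether the type is
#'   one of the nine well-represented types used for cross-type comparison).
#' @examples
#' ecosystemType("polar", "scrub")
#' @export
ecosystemType <- function(climate_band, habitat) {
  climate_band <- as.character(climate_band)
  habitat <- as.character(habitat)
  stopIfNot(all(climate_band %in% CLIMATE_BANDS), "unknown climate band")
  stopIfNot(all(habitat %in% HABITAT_LEVELS), "unknown habitat")
  type <- paste(climate_band, habitat, sep = "_")
  data.frame(ecosystem_type = type,
             retained = type %in% RETAINED_ECOSYSTEM_TYPES,
             stringsAsFactors = FALSE)
}

#' Attach genus and traits to community samples
#'
#' Harmonizes the sample table's taxon names against a checklist, extracts
#' the genus, and joins genus-level body length and morphogroup from a trait
#' table. Records that cannot be identified to genus keep \code{NA} traits
#' and are excluded from mass and metabolism (but not density) downstream.
#'
#' @param cd [CommunityData-class].
#' @param traits data.frame with columns \code{genus}, \code{body_length_mm},
#'   \code{morphogroup}.
#' @param checklist accepted names; defaults to the packaged genus checklist.
#' @param max_distance fuzzy-match threshold passed to [harmonizeTaxon()].
#' @return the input \code{CommunityData} with \code{genus},
#'   \code{body_length_mm} and \code{morphogroup} columns added to its
#'   sample table.
#' @export
attachTraits <- function(cd, traits = defaultTraits(),
                         checklist = defaultChecklist(), max_distance = 2L) {
  s <- communitySamples(cd)
  m <- harmonizeTaxon(unique(s$taxon), checklist, max_distance)
  genus <- m$genus[match(s$taxon, m$raw_name)]
  s$genus <- genus
  i <- match(genus, traits$genus)
  s$body_length_mm <- traits$body_length_mm[i]
  s$morphogroup <- traits$morphogroup[i]
  communityData(s, siteTable(cd), rejectedRows(cd))
}

#' Load the packaged synthetic genus trait table
#'
#' Genus-level mean body lengths (mm) and morphogroup assignments for the
#' genera in the packaged checklist. Lengths are synthetic values within the
#' realistic 0.2-5 mm range, not measured trait data.
#'
#' @return data.frame with columns \code{genus}, \code{body_length_mm},
#'   \code{morphogroup}.
#' @export
defaultTraits <- function() {
  utils::read.delim(system.file("extdata", "genus_traits_synthetic.tsv",
                                package = "springtailMetrics", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
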