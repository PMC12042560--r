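#' Tibiofemoral MOAKS subregion codes
#'
#' The 10 tibiofemoral cartilage subregions used throughout the package:
#' central and posterior femur, medial and lateral (cMF, cLF, pMF, pLF), and
#' anterior, central, posterior tibia, medial and lateral (aMT, cMT, pMT,
#' aLT, cLT, pLT). The anterior femur is excluded by construction because it
#' is partly incorporated in the patellofemoral compartment.
#'
#' @return Character vector of the 10 region codes, in canonical order.
#' @export
region_codes <- function() {
  c("cMF", "cLF", "pMF", "pLF", "aMT", "cMT", "pMT", "aLT", "cLT", "pLT")
}

#' Bone and side of each subregion
#'
#' @return A data.frame with columns `region`, `bone` ("femur"/"tibia") and
#'   `side` ("medial"/"lateral"), one row per subregion code.
#' @export
region_info <- function() {
  codes <- region_codes()
  data.frame(
    region = codes,
    bone = ifelse(substr(codes, nchar(codes), nchar(codes)) == "F",
                  "femur", "tibia"),
    side = ifelse(substr(codes, 2, 2) == "M", "medial", "lateral"),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated region atlas
#'
#' An atlas maps every corresponded bone-surface landmark to exactly one of
#' the 10 tibiofemoral subregions, with an optional dimensionless area
#' weight per landmark (default 1: each landmark represents an equal share
#' of the subregional bone surface area).
#'
#' @param landmark_id Integer vector of unique landmark ids (0-based ids are
#'   conventional but any unique integers are accepted).
#' @param region Character vector of subregion codes, one per landmark.
#' @param area_weight Nonnegative finite numeric weights; recycled scalar 1
#'   by default.
#' @return An object of class `qm_atlas`: a data.frame with columns
#'   `landmark_id`, `region` (factor over [region_codes()]), `area_weight`,
#'   ordered by `landmark_id`.
#' @export
qm_atlas <- function(landmark_id, region, area_weight = 1) {
  landmark_id <- as.integer(landmark_id)
  if (anyNA(landmark_id)) stop("landmark_id must be integer and non-missing")
  if (anyDuplicated(landmark_id)) {
    dup <- unique(landmark_id[duplicated(landmark_id)])
    stop("duplicate landmark_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- !(region %in% region_codes())
  if (any(bad)) {
    stop("unknown region code(s) ", paste(unique(region[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
         "; valid codes: ", paste(region_codes(), collapse = ", "))
  }
  area_weight <- rep_len(as.numeric(area_weight), length(landmark_id))
  if (any(!is.finite(area_weight)) || any(area_weight < 0)) {
    stop("area_weight must be finite and nonnegative")
  }
  atlas <- data.frame(
    landmark_id = landmark_id,
    region = factor(region, levels = region_codes()),
    area_weight = area_weight
  )
  atlas <- atlas[order(atlas$landmark_id), , drop = FALSE]
  rownames(atlas) <- NULL
  missing_regions <- setdiff(region_codes(), as.character(unique(atlas$region)))
  if (length(missing_regions) > 0) {
    stop("atlas must cover all 10 subregions; missing: ",
         paste(missing_regions, collapse = ", "))
  }
  class(atlas) <- c("qm_atlas", "data.frame")
  atlas
}

#' Read a region atlas from CSV
#'
#' Expects header columns `landmark_id`, `region` and optionally
#' `area_weight` (missing or absent weights default to 1).
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @return A validated [qm_atlas()] object.
#' @export
load_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark_id", "region")
  if (!all(need %in% names(df))) {
    stop("atlas CSV must have columns ", paste(need, collapse = ", "))
  }
  w <- if ("area_weight" %in% names(df)) {
    ifelse(is.na(df$area_weight), 1, df$area_weight)
  } else 1
  qm_atlas(df$landmark_id, df$region, w)
}

#' Write a region atlas to CSV
#'
#' @param atlas A [qm_atlas()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "qm_atlas"))
  out <- data.frame(landmark_id = atlas$landmark_id,
                    region = as.character(atlas$region),
                    area_weight = atlas$area_weight)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Landmark indices of one subregion
#'
#' @param atlas A [qm_atlas()] object.
#' @param region A single subregion code.
#' @return Integer positions (row indices into the atlas, equivalently into
#'   any thickness vector on this atlas) of the region's landmarks.
#' @export
region_landmarks <- function(atlas, region) {
  stopifnot(inherits(atlas, "qm_atlas"), region %in% region_codes())
  which(as.character(atlas$region) == region)
}

#' @export
print.qm_atlas <- function(x, ...) {
  cat("<qm_atlas> ", nrow(x), " landmarks over ",
      length(unique(x$region)), " subregions\n", sep = "")
  print(table(region = x$region))
  invisible(x)
}
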