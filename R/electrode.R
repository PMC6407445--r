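# Lead and pulse-generator geometry.
#
# Contacts are indexed 0 (tip-most) to 3 and all offsets are measured in the
# lead frame: axial position in mm from the lead tip along the insertion
# axis (world +x by default), transverse offsets y ("medial/lateral") and
# z ("superior/inferior").

#' Quadripolar SNS lead specifications
#'
#' Builds the geometric specification of one of the two quadripolar
#' Medtronic-style SNS leads. Model 3093 has three 3 mm contacts and one
#' long 10.2 mm contact (contact 1), separated by 1.5 mm; model 3889 has
#' four 3 mm contacts separated by 3 mm. Both are 1.27 mm in diameter.
#'
#' The distance from the physical lead tip to the start of contact 0 is not
#' part of the published contact geometry; it defaults to 1.5 mm and is
#' configurable. `shaft_length_mm` defaults to the end of contact 3 plus
#' 10 mm of insulated shaft.
#'
#' @param model_id lead model, `3093` or `3889` (integer or character).
#' @param tip_offset_mm distance from lead tip to the start of contact 0 (mm).
#' @param shaft_length_mm total modelled shaft length from the tip (mm);
#'   `NULL` for the default.
#' @return An object of class `sns_electrode`: list with `model_id`,
#'   `diameter_mm`, `contact_lengths_mm`, `gap_mm`, `tip_offset_mm`,
#'   `shaft_length_mm`.
#' @examples
#' make_electrode(3093)
#' contact_extents(make_electrode(3889))
#' @export
make_electrode <- function(model_id, tip_offset_mm = 1.5,
                           shaft_length_mm = NULL) {
  key <- as.character(model_id)
  specs <- list(
    "3093" = list(lengths = c(3.0, 10.2, 3.0, 3.0), gap = 1.5),
    "3889" = list(lengths = c(3.0, 3.0, 3.0, 3.0), gap = 3.0)
  )
  if (!key %in% names(specs)) {
    stop("unknown lead model '", key, "'; valid models are 3093 and 3889",
         call. = FALSE)
  }
  stopifnot(tip_offset_mm >= 0)
  sp <- specs[[key]]
  span <- sum(sp$lengths) + 3 * sp$gap
  if (is.null(shaft_length_mm)) shaft_length_mm <- tip_offset_mm + span + 10
  if (shaft_length_mm < tip_offset_mm + span) {
    stop("shaft_length_mm shorter than the contact array", call. = FALSE)
  }
  structure(list(
    model_id = key,
    diameter_mm = 1.27,
    contact_lengths_mm = sp$lengths,
    gap_mm = sp$gap,
    tip_offset_mm = tip_offset_mm,
    shaft_length_mm = shaft_length_mm
  ), class = "sns_electrode")
}

#' @export
print.sns_electrode <- function(x, ...) {
  cat("SNS lead model", x$model_id, "\n")
  cat("  diameter:", x$diameter_mm, "mm\n")
  ext <- contact_extents(x)
  for (k in 0:3) {
    cat(sprintf("  contact %d: [%.1f, %.1f] mm from tip (%.1f mm long)\n",
                k, ext[k + 1, "start"], ext[k + 1, "end"],
                x$contact_lengths_mm[k + 1]))
  }
  invisible(x)
}

#' Axial extents of the lead contacts
#'
#' Start/end positions of the four contact bands along the lead axis,
#' measured in mm from the lead tip.
#'
#' @param spec an `sns_electrode` from [make_electrode()].
#' @param tip_offset_mm override for the tip-to-contact-0 distance; defaults
#'   to the value in `spec`.
#' @return A 4 x 2 matrix with columns `start` and `end`; row `k + 1` is
#'   contact `k`.
#' @export
contact_extents <- function(spec, tip_offset_mm = spec$tip_offset_mm) {
  stopifnot(inherits(spec, "sns_electrode"), tip_offset_mm >= 0)
  starts <- numeric(4)
  ends <- numeric(4)
  pos <- tip_offset_mm
  for (k in seq_len(4)) {
    starts[k] <- pos
    ends[k] <- pos + spec$contact_lengths_mm[k]
    pos <- ends[k] + spec$gap_mm
  }
  out <- cbind(start = starts, end = ends)
  rownames(out) <- paste0("contact", 0:3)
  out
}

#' Implanted pulse generator specification
#'
#' The IPG is modelled as an axis-aligned cuboid, 55 x 60 x 10 mm by
#' default, placed in the subcutaneous tissue; it serves as the anodic
#' return in monopolar stimulation and is insulated otherwise.
#'
#' @param centre_mm world coordinates of the cuboid centre (mm).
#' @param dims_mm edge lengths (mm); default `c(55, 60, 10)`.
#' @return An object of class `sns_ipg`.
#' @export
ipg_spec <- function(centre_mm, dims_mm = c(55, 60, 10)) {
  centre_mm <- as.numeric(centre_mm)
  dims_mm <- as.numeric(dims_mm)
  stopifnot(length(centre_mm) == 3, length(dims_mm) == 3, all(dims_mm > 0))
  structure(list(centre_mm = centre_mm, dims_mm = dims_mm),
            class = "sns_ipg")
}

#' Lead placement
#'
#' Pose of the implanted lead: tip position in world mm and a unit insertion
#' axis. The contact array extends from the tip along `axis`.
#'
#' @param tip_mm world coordinates of the lead tip (mm).
#' @param axis direction of the shaft from the tip; normalised internally
#'   and must be non-zero. Default `c(1, 0, 0)`.
#' @return An object of class `sns_placement`.
#' @export
placement <- function(tip_mm, axis = c(1, 0, 0)) {
  tip_mm <- as.numeric(tip_mm)
  axis <- as.numeric(axis)
  stopifnot(length(tip_mm) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("placement axis must be non-zero", call. = FALSE)
  axis <- axis / nrm
  stopifnot(abs(sqrt(sum(axis^2)) - 1) < 1e-9)
  structure(list(tip_mm = tip_mm, axis = axis), class = "sns_placement")
}
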