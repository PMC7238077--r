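# The i2b2-2014-style PHI label inventory. Where a general class has
# subclasses, only the subclasses are used as labels; Profession, Age and
# Date have none and stand for themselves.

.phi_subclasses <- list(
  name           = c("patient", "clinician", "username"),
  profession     = "profession",
  location       = c("hospital", "organization", "street", "city", "state",
                     "country", "zip", "location-other"),
  age            = "age",
  date           = "date",
  contact        = c("phone", "fax", "email", "url", "ip-address"),
  identification = c("social-security-number", "medical-record-number",
                     "health-plan-number", "account-number", "license-number",
                     "vehicle-id", "device-id", "biometric-id", "id-number")
)

# Subclasses annotated as absent from the published challenge data.
.absent_phi_labels <- c("ip-address", "social-security-number",
                        "account-number", "license-number", "vehicle-id")

.non_phi_label <- "non-PHI"

#' Build the 29-label PHI annotation scheme
#'
#' Returns the label scheme used throughout the package: 28 PHI labels (the
#' subclasses of Name, Location, Contact and Identification plus the
#' subclass-free classes Profession, Age and Date) and the `"non-PHI"` label.
#'
#' @return an object of class `label_scheme` with elements
#'   `labels` (character, length 29, `"non-PHI"` last),
#'   `phi_labels` (character, length 28),
#'   `present_phi_labels` (the 23 PHI labels attested in the published
#'   challenge data), and `general_class` (named character mapping each PHI
#'   label to its general class).
#' @examples
#' scheme <- build_label_scheme()
#' length(scheme$labels)
#' label_index(scheme, "date")
#' is_phi_label(scheme, c("date", "non-PHI"))
#' @export
build_label_scheme <- function() {
  phi <- unname(unlist(.phi_subclasses))
  general <- rep(names(.phi_subclasses), lengths(.phi_subclasses))
  scheme <- list(
    labels = c(phi, .non_phi_label),
    phi_labels = phi,
    present_phi_labels = setdiff(phi, .absent_phi_labels),
    absent_phi_labels = .absent_phi_labels,
    general_class = setNames(general, phi)
  )
  class(scheme) <- "label_scheme"
  scheme
}

#' Map label names to 0-based integer indices
#'
#' @param scheme a `label_scheme`.
#' @param labels character vector of label names.
#' @return integer vector in `0:28`; unknown labels are an error.
#' @export
label_index <- function(scheme, labels) {
  idx <- match(labels, scheme$labels)
  if (anyNA(idx)) {
    stop_phideid("unknown label(s): %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Test whether labels denote PHI
#'
#' @param scheme a `label_scheme`.
#' @param labels character vector of label names (must belong to the scheme).
#' @return logical vector; `FALSE` only for `"non-PHI"`.
#' @export
is_phi_label <- function(scheme, labels) {
  label_index(scheme, labels) # validates
  labels != .non_phi_label
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("PHI label scheme: %d labels (%d PHI + %s)\n",
              length(x$labels), length(x$phi_labels), .non_phi_label))
  cat("  PHI:", paste(x$phi_labels, collapse = ", "), "\n")
  invisible(x)
}
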