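#' Cylindrical insert phantom
#'
#' A 2-D phantom: an outer cylinder of a bulk material containing
#' non-overlapping cylindrical inserts. Coordinates are in mm with the
#' origin at the rotation centre.
#'
#' @param outer_material A `material_spec` for the bulk cylinder.
#' @param outer_diameter_mm Outer cylinder diameter (mm).
#' @param inserts Data frame with columns `material` (list-column of
#'   `material_spec`), `x`, `y` (centre, mm) and `diameter` (mm). May have
#'   zero rows.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_material, outer_diameter_mm, inserts) {
  stopifnot(inherits(outer_material, "material_spec"))
  r_out <- outer_diameter_mm / 2
  if (nrow(inserts)) {
    r_in <- inserts$diameter / 2
    if (any(sqrt(inserts$x^2 + inserts$y^2) + r_in > r_out + 1e-9))
      stop("inserts must lie inside the outer cylinder")
    if (nrow(inserts) > 1) {
      for (i in seq_len(nrow(inserts) - 1)) for (j in (i + 1):nrow(inserts)) {
        d <- sqrt((inserts$x[i] - inserts$x[j])^2 +
                  (inserts$y[i] - inserts$y[j])^2)
        if (d < r_in[i] + r_in[j] - 1e-9) stop("inserts must not overlap")
      }
    }
  }
  structure(list(outer_material = outer_material,
                 outer_diameter_mm = outer_diameter_mm, inserts = inserts),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %.1f mm %s cylinder, %d inserts\n",
              x$outer_diameter_mm, x$outer_material$name, nrow(x$inserts)))
  if (nrow(x$inserts)) {
    nm <- vapply(x$inserts$material, function(m) m$name, character(1))
    cat(" ", paste(sprintf("%s (%.1f mm)", nm, x$inserts$diameter),
                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default insert phantom
#'
#' A 20 mm PMMA cylinder holding six 4 mm material inserts (water, oil,
#' PC, PEEK, POM, PTFE) arranged on a 6 mm radius ring, with a central 4 mm
#' air cavity.
#'
#' @return A `phantom_spec`.
#' @export
default_phantom <- function() {
  lib <- materials()
  names6 <- c("water", "oil", "pc", "peek", "pom", "ptfe")
  ang <- (seq_along(names6) - 1) * 2 * pi / length(names6)
  inserts <- data.frame(x = c(6 * cos(ang), 0), y = c(6 * sin(ang), 0),
                        diameter = 4)
  inserts$material <- I(c(lib[names6], list(lib$air)))
  inserts$name <- c(names6, "air")
  phantom_spec(lib$pmma, 20, inserts)
}

#' Parallel-beam path lengths through a phantom
#'
#' For rays perpendicular to the detector at rotation angle `angle_deg`,
#' computes each ray's intersection length with the outer cylinder and with
#' each insert. The bulk-material path is the outer chord minus the insert
#' chords (inserts displace the bulk).
#'
#' @param phantom A `phantom_spec`.
#' @param angle_deg Projection angle in degrees (counter-clockwise).
#' @param s_mm Vector of ray positions on the detector axis (mm, signed
#'   distance from the rotation centre).
#' @return Matrix `[length(s_mm), 1 + n_inserts]` of path lengths in mm;
#'   column 1 is the bulk material, then one column per insert, with the
#'   materials in `attr(, "materials")`.
#' @export
path_lengths <- function(phantom, angle_deg, s_mm) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))   # detector axis direction in object frame
  chord <- function(cx, cy, r) {
    d <- abs(cx * u[1] + cy * u[2] - s_mm)
    2 * sqrt(pmax(r^2 - d^2, 0))
  }
  n_ins <- nrow(phantom$inserts)
  L <- matrix(0, length(s_mm), 1 + n_ins)
  L[, 1] <- chord(0, 0, phantom$outer_diameter_mm / 2)
  mats <- list(phantom$outer_material)
  if (n_ins) {
    for (i in seq_len(n_ins)) {
      L[, i + 1] <- chord(phantom$inserts$x[i], phantom$inserts$y[i],
                          phantom$inserts$diameter[i] / 2)
      mats[[i + 1]] <- phantom$inserts$material[[i]]
    }
    L[, 1] <- L[, 1] - rowSums(L[, -1, drop = FALSE])
  }
  attr(L, "materials") <- mats
  L
}
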