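# Bundled energy-indexed physics tables and the interpolation contract every
# physics operation in the package goes through.

#' Material densities used to convert mass coefficients to linear ones
#'
#' Densities in g/cm^3: aluminum 2.699, dry air 1.205e-3 (20 degrees C).
#'
#' @format Named numeric vector.
#' @export
material_density <- c(aluminum = 2.699, air = 1.205e-3)

# cache of loaded tables, filled lazily
.ref_env <- new.env(parent = emptyenv())

#' List the bundled reference tables
#'
#' Returns the manifest of energy-indexed coefficient tables shipped with the
#' package: photon mass attenuation and mass energy-absorption coefficients
#' for aluminum, air and tungsten, and the Hp(3)/air-kerma conversion
#' coefficient for photons at normal incidence on the cylinder head phantom
#' (a synthetic Behrens-type compilation, see the table's `source` column).
#'
#' @return A data.frame with one row per bundled table (name, file, quantity,
#'   material, units, interpolation rule, geometry, source).
#' @export
reference_manifest <- function() {
  path <- system.file("extdata", "manifest.csv", package = "ctlensdose",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a bundled reference table
#'
#' @param name Table name as listed by [reference_manifest()], e.g.
#'   `"mu_rho_aluminum"` or `"hp3_ka"`.
#' @return An object of class `ref_table`: a list with `name`, `quantity`,
#'   `energy_keV` (strictly increasing), `value` (all positive),
#'   `interpolation` (`"loglog"` or `"linear"`) and `source`.
#' @examples
#' tab <- reference_table("hp3_ka")
#' ref_interp(tab, 56.47)
#' @export
reference_table <- function(name) {
  if (!is.null(.ref_env[[name]])) return(.ref_env[[name]])
  man <- reference_manifest()
  row <- man[man$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown reference table '", name, "'; available: ",
         paste(man$name, collapse = ", "))
  path <- system.file("extdata", row$file, package = "ctlensdose",
                      mustWork = TRUE)
  dat <- utils::read.csv(path)
  tab <- new_ref_table(name = name,
                       quantity = row$quantity,
                       material = row$material_or_phantom,
                       energy_keV = dat$energy_keV,
                       value = dat$value,
                       interpolation = row$interpolation,
                       source = row$source)
  .ref_env[[name]] <- tab
  tab
}

#' Construct a reference table from vectors
#'
#' Mostly useful for tests and user-supplied tabulations; bundled tables are
#' loaded with [reference_table()].
#'
#' @param name,quantity,material,source Free-text labels.
#' @param energy_keV Strictly increasing photon energies in keV, all > 0.
#' @param value Positive coefficients, one per energy.
#' @param interpolation `"loglog"` (attenuation-type data) or `"linear"`
#'   (conversion coefficients).
#' @return A `ref_table` object.
#' @export
new_ref_table <- function(name, energy_keV, value,
                          interpolation = c("loglog", "linear"),
                          quantity = name, material = "", source = "") {
  interpolation <- match.arg(interpolation)
  energy_keV <- as.numeric(energy_keV)
  value <- as.numeric(value)
  if (length(energy_keV) < 2L || length(energy_keV) != length(value))
    stop("table '", name, "': need >= 2 (energy, value) pairs")
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0))
    stop("table '", name, "': energies must be finite and > 0")
  if (any(diff(energy_keV) <= 0))
    stop("table '", name, "': energies must be strictly increasing")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("table '", name, "': values must be finite and > 0")
  structure(list(name = name, quantity = quantity, material = material,
                 energy_keV = energy_keV, value = value,
                 interpolation = interpolation, source = source),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat("Reference table '", x$name, "' (", x$quantity, ", ", x$material,
      ")\n", sep = "")
  cat("  ", length(x$energy_keV), " nodes, ", min(x$energy_keV), "-",
      max(x$energy_keV), " keV, ", x$interpolation, " interpolation\n",
      sep = "")
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Interpolate a reference table at given photon energies
#'
#' Attenuation-type tables (`interpolation = "loglog"`) are interpolated
#' linearly in log(energy) vs log(value), which is exact for power-law
#' segments and is the standard convention for photon cross-section data;
#' conversion-coefficient tables are interpolated linearly. Queries at a
#' tabulated node return the node value exactly.
#'
#' @param table A `ref_table`.
#' @param energy_keV Numeric vector of query energies in keV; every energy
#'   must lie within the tabulated range.
#' @return Numeric vector of interpolated coefficients.
#' @export
ref_interp <- function(table, energy_keV) {
  stopifnot(inherits(table, "ref_table"))
  e <- table$energy_keV
  if (any(!is.finite(energy_keV)))
    stop("table '", table$name, "': non-finite query energy")
  if (any(energy_keV < e[1L] | energy_keV > e[length(e)]))
    stop("table '", table$name, "': energy outside tabulated range [",
         e[1L], ", ", e[length(e)], "] keV")
  if (table$interpolation == "loglog") {
    out <- exp(stats::approx(log(e), log(table$value), xout = log(energy_keV),
                             ties = "ordered")$y)
  } else {
    out <- stats::approx(e, table$value, xout = energy_keV,
                         ties = "ordered")$y
  }
  # guarantee bit-exact node reproduction (log/exp round trip can wobble)
  hit <- match(energy_keV, e)
  idx <- which(!is.na(hit))
  out[idx] <- table$value[hit[idx]]
  out
}

# linear attenuation coefficient (1/cm) for a bundled material
linear_mu <- function(material, energy_keV) {
  tab <- switch(material,
    aluminum = reference_table("mu_rho_aluminum"),
    air      = reference_table("mu_rho_air"),
    tungsten = reference_table("mu_rho_tungsten"),
    stop("no attenuation table for material '", material,
         "'; supported: aluminum, air, tungsten"))
  dens <- switch(material, aluminum = material_density[["aluminum"]],
                 air = material_density[["air"]],
                 tungsten = 19.30)
  ref_interp(tab, energy_keV) * dens
}
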