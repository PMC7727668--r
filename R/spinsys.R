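#' Declare a proton spin system
#'
#' A spin system bundles everything the Liouvillian needs: site labels,
#' chemical shifts (ppm), the scalar-coupling matrix (Hz) and, optionally,
#' Cartesian coordinates (angstrom) from which dipolar couplings are
#' derived. Only 1H sites are supported; exchangeable N-H/O-H protons
#' should not be declared since they do not contribute to intramolecular
#' dipolar relaxation in deuterated solvent.
#'
#' @param name molecule name.
#' @param labels character vector of site names (e.g. `c("Hb2","Hb3","Ha")`).
#' @param shifts numeric vector of chemical shifts in ppm, one per site.
#' @param j_matrix symmetric numeric matrix of scalar couplings in Hz with
#'   zero diagonal, or `NULL` for an uncoupled system.
#' @param coords optional numeric matrix (n x 3) of Cartesian positions in
#'   angstrom, rows in site order.
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system("pair", c("H1", "H2"), c(4.1, 3.9),
#'                    j_matrix = matrix(c(0, 10, 10, 0), 2),
#'                    coords = rbind(c(0, 0, 0), c(1.77, 0, 0)))
#' sys
#' @export
spin_system <- function(name, labels, shifts, j_matrix = NULL, coords = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(j_matrix)) {
    j_matrix <- matrix(0, n, n)
  }
  j_matrix <- as.matrix(j_matrix)
  dimnames(j_matrix) <- list(labels, labels)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    rownames(coords) <- labels
    colnames(coords) <- c("x", "y", "z")
  }
  sys <- structure(
    list(name = as.character(name)[1], labels = labels,
         shifts = stats::setNames(as.numeric(shifts), labels),
         j_matrix = j_matrix, coords = coords),
    class = "spin_system"
  )
  validate_spin_system(sys)
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> ", x$name, ": ", n_spins(x), " proton site(s)\n", sep = "")
  df <- tibble::tibble(site = x$labels, shift_ppm = unname(x$shifts))
  if (!is.null(x$coords)) {
    df$x <- x$coords[, 1]; df$y <- x$coords[, 2]; df$z <- x$coords[, 3]
  }
  print(df)
  if (any(x$j_matrix != 0)) {
    cat("J couplings (Hz):\n")
    print(round(x$j_matrix, 3))
  }
  invisible(x)
}

#' Number of spins in a system
#' @param sys a `spin_system`.
#' @return integer spin count.
#' @export
n_spins <- function(sys) length(sys$labels)

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "spinlls_schema_error", ...)
}

#' Validate a spin system
#'
#' Checks the structural invariants: unique labels, finite shifts, a
#' symmetric zero-diagonal J matrix, a site count within the supported cap
#' and, when coordinates are present, all interproton distances above a
#' 0.5-angstrom physical sanity bound.
#'
#' @param sys a `spin_system`.
#' @return `sys`, invisibly unchanged, or an error of class
#'   `spinlls_schema_error` naming the offending field.
#' @export
validate_spin_system <- function(sys) {
  n <- length(sys$labels)
  cap <- .spinlls_cap()
  if (n < 1) abort_schema("spin system must declare at least one site")
  if (n > cap) {
    abort_schema(sprintf(
      "spin system has %d sites but the dense-superoperator cap is %d; select a proton subsystem",
      n, cap))
  }
  if (anyDuplicated(sys$labels)) abort_schema("duplicate site labels")
  if (length(sys$shifts) != n || any(!is.finite(sys$shifts))) {
    abort_schema("field 'shifts': need one finite value per site")
  }
  j <- sys$j_matrix
  if (!is.matrix(j) || any(dim(j) != n) || any(!is.finite(j))) {
    abort_schema("field 'j_matrix': must be a finite n x n matrix")
  }
  if (any(abs(j - t(j)) > 1e-12)) {
    abort_schema("field 'j_matrix': asymmetric couplings (J[i,j] != J[j,i])")
  }
  if (any(abs(diag(j)) > 0)) abort_schema("field 'j_matrix': nonzero diagonal")
  if (!is.null(sys$coords)) {
    xyz <- sys$coords
    if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3 || any(!is.finite(xyz))) {
      abort_schema("field 'coords': must be a finite n x 3 matrix")
    }
    if (n > 1) {
      d <- stats::dist(xyz)
      if (any(d <= 0.5)) {
        abort_schema("field 'coords': interproton distance <= 0.5 angstrom is unphysical")
      }
    }
  }
  invisible(sys)
}

#' Read a spin system from file
#'
#' Accepts a YAML or JSON document with keys `name`, `sites` (each a list
#' with `label`, `shift_ppm` and optionally `xyz_angstrom`) and `couplings`
#' (a list of `[label_i, label_j, hz]` triples). Coordinates may instead be
#' supplied through a `coords_xyz` key naming a standard XYZ file whose
#' atom order matches the site order.
#'
#' @param path path to the document.
#' @return a validated [spin_system()].
#' @export
load_spin_system <- function(path) {
  if (!file.exists(path)) {
    abort_schema(sprintf("spin-system file not found: %s", path))
  }
  doc <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    abort_schema(sprintf("cannot parse spin-system file '%s': %s", path, conditionMessage(e)))
  })
  for (key in c("name", "sites")) {
    if (is.null(doc[[key]])) abort_schema(sprintf("missing field '%s'", key))
  }
  sites <- doc$sites
  labels <- vapply(sites, function(s) {
    if (is.null(s$label)) abort_schema("missing field 'sites[].label'")
    as.character(s$label)
  }, character(1))
  shifts <- vapply(sites, function(s) {
    if (is.null(s$shift_ppm) || !is.numeric(s$shift_ppm) || !is.finite(s$shift_ppm)) {
      abort_schema(sprintf("field 'shift_ppm' missing or non-finite for site '%s'", s$label))
    }
    as.numeric(s$shift_ppm)
  }, numeric(1))
  n <- length(labels)

  coords <- NULL
  has_xyz <- vapply(sites, function(s) !is.null(s$xyz_angstrom), logical(1))
  if (!is.null(doc$coords_xyz)) {
    xyz_path <- doc$coords_xyz
    if (!file.exists(xyz_path)) {
      xyz_path <- file.path(dirname(path), doc$coords_xyz)
    }
    coords <- read_xyz(xyz_path, n_expected = n)
  } else if (all(has_xyz)) {
    coords <- t(vapply(sites, function(s) {
      v <- as.numeric(unlist(s$xyz_angstrom))
      if (length(v) != 3 || any(!is.finite(v))) {
        abort_schema(sprintf("field 'xyz_angstrom' for site '%s' must be 3 finite numbers", s$label))
      }
      v
    }, numeric(3)))
  } else if (any(has_xyz)) {
    abort_schema("field 'xyz_angstrom': give coordinates for all sites or none")
  }

  jm <- matrix(0, n, n, dimnames = list(labels, labels))
  for (cp in doc$couplings %||% list()) {
    cp <- unlist(cp, use.names = FALSE)
    if (length(cp) != 3) abort_schema("field 'couplings': each entry must be [label_i, label_j, hz]")
    li <- as.character(cp[1]); lj <- as.character(cp[2])
    hz <- suppressWarnings(as.numeric(cp[3]))
    if (!li %in% labels) abort_schema(sprintf("coupling references unknown site '%s'", li))
    if (!lj %in% labels) abort_schema(sprintf("coupling references unknown site '%s'", lj))
    if (li == lj) abort_schema(sprintf("coupling must reference two distinct sites, got '%s'", li))
    if (!is.finite(hz)) abort_schema(sprintf("non-finite coupling for pair (%s, %s)", li, lj))
    if (jm[li, lj] != 0 && abs(jm[li, lj] - hz) > 1e-12) {
      abort_schema(sprintf("field 'couplings': J(%s,%s) declared twice with different values", li, lj))
    }
    jm[li, lj] <- hz
    jm[lj, li] <- hz
  }
  spin_system(doc$name, labels, shifts, jm, coords)
}

#' Write a spin system to file
#'
#' Writes the YAML document read back by [load_spin_system()]. Numbers are
#' serialized at full double precision so a write/load round trip is
#' bit-identical.
#'
#' @param sys a `spin_system`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(sys, path) {
  sites <- lapply(seq_along(sys$labels), function(i) {
    s <- list(label = sys$labels[i], shift_ppm = unname(sys$shifts[i]))
    if (!is.null(sys$coords)) s$xyz_angstrom <- as.numeric(sys$coords[i, ])
    s
  })
  cps <- list()
  n <- length(sys$labels)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sys$j_matrix[i, j] != 0) {
        cps[[length(cps) + 1L]] <- list(sys$labels[i], sys$labels[j], sys$j_matrix[i, j])
      }
    }
  }
  doc <- list(name = sys$name, sites = sites, couplings = cps)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 17)
  }
  invisible(path)
}

#' Read Cartesian coordinates from a standard XYZ file
#'
#' @param path XYZ file: atom count, comment line, then `element x y z`.
#' @param n_expected optional expected atom count; mismatch is an error.
#' @return numeric matrix (n x 3) in angstrom.
#' @export
read_xyz <- function(path, n_expected = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("XYZ file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3) abort_schema(sprintf("XYZ file too short: %s", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort_schema(sprintf("XYZ file '%s': first line must be the atom count", path))
  if (length(lines) < 2 + n) abort_schema(sprintf("XYZ file '%s': fewer atom lines than declared", path))
  rows <- lapply(lines[3:(2 + n)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 4) abort_schema(sprintf("XYZ file '%s': malformed atom line '%s'", path, ln))
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(!is.finite(v))) abort_schema(sprintf("XYZ file '%s': non-numeric coordinates in '%s'", path, ln))
    v
  })
  xyz <- do.call(rbind, rows)
  if (!is.null(n_expected) && nrow(xyz) != n_expected) {
    abort_schema(sprintf("XYZ file '%s': %d atoms but %d sites declared", path, nrow(xyz), n_expected))
  }
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
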