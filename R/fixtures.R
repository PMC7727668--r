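`%||%` <- function(a, b) if (is.null(a)) b else a

# --- idealized geometry templates -------------------------------------------
#
# Triad: a methylene Hb2/Hb3 pair plus the vicinal Ha, built from tetrahedral
# carbons (C-C 1.526 A, H-C-H and H-C-C angles 109.4712 deg) in a staggered
# conformation. The C-Hb length is scaled so the geminal H-H distance is
# exactly r_gem; C-Ha is 1.09 A. Two staggered rotamers are available:
#   "bisector"  Ha gauche (+/-60 deg dihedral) to both Hb's, equal vicinal
#               distances -- the heavy side-chain substituent anti to Ha;
#               keeps the fixture symmetric under Hb2 <-> Hb3 exchange.
#   "anti"      Ha anti (180 deg) to Hb3 and gauche to Hb2 -- the generic
#               energy-minimum rotamer of alpha-amino acids, where the heavy
#               substituent sits gauche to the backbone.
.triad_coords <- function(r_gem = 1.77, rotamer = c("bisector", "anti")) {
  rotamer <- match.arg(rotamer)
  cc <- 1.526
  cos_t <- -1 / 3                      # tetrahedral angle cosine
  sin_t <- sqrt(1 - cos_t^2)
  l_b <- r_gem / (2 * sin(acos(cos_t) / 2))
  hb2 <- l_b * c(cos_t, sin_t * cos(pi / 3),  sin_t * sin(pi / 3))
  hb3 <- l_b * c(cos_t, sin_t * cos(pi / 3), -sin_t * sin(pi / 3))
  phi <- if (rotamer == "bisector") 0 else 2 * pi / 3
  ha  <- c(cc, 0, 0) + 1.09 * c(-cos_t, sin_t * cos(phi), sin_t * sin(phi))
  rbind(Hb2 = hb2, Hb3 = hb3, Ha = ha)
}

# Trans-olefinic pair: planar HC=CH fragment with textbook sp2 parameters
# (C=C 1.33 A, C-H 1.085 A, H-C=C 123 deg), protons trans across the double
# bond. Gives r(H-H) ~ 3.10 A.
.trans_olefinic_coords <- function() {
  cc <- 1.33; ch <- 1.085; ang <- 123 * pi / 180
  h1 <- ch * c(cos(ang), sin(ang), 0)
  h2 <- c(cc, 0, 0) - ch * c(cos(ang), sin(ang), 0)
  rbind(H2 = h1, H3 = h2)
}

# --- vendored metabolite parameters -----------------------------------------
#
# Shifts are literature values for the zwitterions in D2O near neutral pH
# (BMRB-style, ppm from DSS); J couplings for Ser/Asn/Asp/His are the values
# tabulated in the study this package reproduces, Cys couplings are standard
# literature values. Geometries are the idealized templates above, not the
# (unpublished) DFT structures, and are therefore synthetic stand-ins.
.metabolites <- list(
  Ser = list(labels = c("Hb2", "Hb3", "Ha"),
             shifts = c(3.962, 3.888, 3.834),
             j = c(is = -10.52, ir = 4.81, sr = 1.32), kind = "triad"),
  Cys = list(labels = c("Hb2", "Hb3", "Ha"),
             shifts = c(3.038, 2.966, 3.958),
             j = c(is = -14.40, ir = 4.30, sr = 7.00), kind = "triad"),
  Asn = list(labels = c("Hb2", "Hb3", "Ha"),
             shifts = c(2.949, 2.863, 4.006),
             j = c(is = -13.55, ir = 5.65, sr = 1.64), kind = "triad"),
  Asp = list(labels = c("Hb2", "Hb3", "Ha"),
             shifts = c(2.801, 2.653, 3.891),
             j = c(is = -13.41, ir = 5.51, sr = 1.55), kind = "triad"),
  His = list(labels = c("Hb2", "Hb3", "Ha"),
             shifts = c(3.230, 3.160, 3.990),
             j = c(is = -13.68, ir = 5.78, sr = 1.43), kind = "triad"),
  Gly = list(labels = c("Ha2", "Ha3"), shifts = c(3.55, 3.55),
             j = c(is = -17.5), kind = "pair_gem"),
  fumarate = list(labels = c("H2", "H3"), shifts = c(6.52, 6.52),
                  j = c(is = 15.8), kind = "olefinic"),
  dimethylfumarate = list(labels = c("H2", "H3"), shifts = c(6.88, 6.88),
                          j = c(is = 15.8), kind = "olefinic")
)

#' Synthesize a spin-system fixture
#'
#' Builds fully populated spin systems from idealized templates:
#' \describe{
#'   \item{`pair`}{two protons at distance `r` with shift difference
#'     `delta_ppm` and coupling `j_hz`.}
#'   \item{`equivalent_pair`}{same with zero shift difference (a fumarate-like
#'     chemically equivalent pair).}
#'   \item{`geminal_triad`}{a methylene Hb2/Hb3 pair (geminal distance `r`,
#'     default 1.77 angstrom) plus the vicinal Ha at idealized tetrahedral
#'     staggered-geometry distances, with couplings `j_is` (geminal),
#'     `j_ir`, `j_sr` (vicinal).}
#'   \item{`named_metabolite`}{vendored literature shifts and couplings for
#'     `name` in `r fixture_metabolites()` placed on the idealized triad or
#'     trans-olefinic template.}
#' }
#'
#' @param kind one of `"pair"`, `"equivalent_pair"`, `"geminal_triad"`,
#'   `"named_metabolite"`.
#' @param name metabolite name for `kind = "named_metabolite"`.
#' @param r interproton (pair) or geminal (triad) distance, angstrom.
#' @param delta_ppm chemical-shift difference of the pair, ppm.
#' @param center_ppm mean chemical shift of the pair, ppm.
#' @param j_hz pair scalar coupling, Hz.
#' @param j_is,j_ir,j_sr triad couplings, Hz.
#' @param shifts optional length-3 shift override for triads, ppm.
#' @return a validated [spin_system()].
#' @examples
#' make_fixture("equivalent_pair", r = 3.10)
#' make_fixture("named_metabolite", name = "Asn")
#' @export
make_fixture <- function(kind = c("pair", "equivalent_pair", "geminal_triad",
                                  "named_metabolite"),
                         name = NULL, r = NULL, delta_ppm = NULL,
                         center_ppm = 4, j_hz = NULL,
                         j_is = NULL, j_ir = NULL, j_sr = NULL, shifts = NULL) {
  kind <- rlang::arg_match(kind)
  if (kind %in% c("pair", "equivalent_pair")) {
    r <- r %||% 1.77
    if (r <= 0) abort_schema("pair distance r must be positive")
    delta <- if (kind == "equivalent_pair") 0 else (delta_ppm %||% 0.1)
    j <- j_hz %||% 10
    spin_system(kind, c("H1", "H2"),
                center_ppm + c(delta / 2, -delta / 2),
                matrix(c(0, j, j, 0), 2),
                rbind(c(0, 0, 0), c(r, 0, 0)))
  } else if (kind == "geminal_triad") {
    r <- r %||% 1.77
    if (r <= 0) abort_schema("geminal distance r must be positive")
    jm <- .triad_j(j_is %||% -12, j_ir %||% 5, j_sr %||% 1.5)
    sh <- shifts %||% c(3.95, 3.88, 3.84)
    spin_system("geminal_triad", c("Hb2", "Hb3", "Ha"), sh, jm, .triad_coords(r))
  } else {
    if (is.null(name) || !name %in% names(.metabolites)) {
      abort_schema(sprintf(
        "unknown metabolite '%s'; available: %s",
        name %||% "<missing>", paste(names(.metabolites), collapse = ", ")))
    }
    m <- .metabolites[[name]]
    if (m$kind == "triad") {
      jm <- .triad_j(m$j[["is"]], m$j[["ir"]], m$j[["sr"]])
      spin_system(name, m$labels, shifts %||% m$shifts, jm,
                  .triad_coords(r %||% 1.77, rotamer = "anti"))
    } else {
      xyz <- if (m$kind == "olefinic") .trans_olefinic_coords() else {
        r0 <- r %||% 1.77
        rbind(c(0, 0, 0), c(r0, 0, 0))
      }
      j <- m$j[["is"]]
      spin_system(name, m$labels, m$shifts, matrix(c(0, j, j, 0), 2), xyz)
    }
  }
}

.triad_j <- function(j_is, j_ir, j_sr) {
  jm <- matrix(0, 3, 3)
  jm[1, 2] <- jm[2, 1] <- j_is
  jm[1, 3] <- jm[3, 1] <- j_ir
  jm[2, 3] <- jm[3, 2] <- j_sr
  jm
}

#' Names of the vendored metabolite fixtures
#' @return character vector of names accepted by
#'   `make_fixture("named_metabolite", name = ...)`.
#' @export
fixture_metabolites <- function() names(.metabolites)
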