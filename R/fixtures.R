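# Programmatic test-molecule catalog.  All geometries are generated from
# idealized internal coordinates (standard bond lengths and angles), so the
# package is fully testable without external data.

# place atom by internal coordinates relative to atoms i (distance),
# j (angle, degrees), k (dihedral, degrees); NeRF construction
.zplace <- function(coords, i, j, k, r, theta, phi) {
  b <- coords[i, ]
  if (is.na(j)) return(b + c(r, 0, 0))
  a <- coords[j, ]
  if (is.na(k)) {
    # in the xy plane
    u <- (b - a) / sqrt(sum((b - a)^2))
    th <- theta * pi / 180
    perp <- c(-u[2], u[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
    perp <- perp / sqrt(sum(perp^2))
    return(b + r * (-cos(th) * u + sin(th) * perp))
  }
  cpos <- coords[k, ]
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- b - a; bc <- bc / sqrt(sum(bc^2))
  ab <- a - cpos
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  b + d[1] * bc + d[2] * m + d[3] * n
}

# build coordinates from a z-matrix: list of c(i, j, k, r, theta, phi)
.zbuild <- function(zm) {
  n <- length(zm) + 1L
  coords <- matrix(0, n, 3)
  for (t in seq_along(zm)) {
    e <- zm[[t]]
    coords[t + 1L, ] <- .zplace(coords, e[1], e[2], e[3], e[4], e[5], e[6])
  }
  coords
}

#' Built-in test molecules
#'
#' Returns one of the package's programmatically generated fixtures:
#' \describe{
#'   \item{h2, h2_stretched}{H2 at 0.74 / 1.50 Angstrom.}
#'   \item{he_dimer}{two He atoms (separation via `d`, default 3 Angstrom).}
#'   \item{water, water_dimer}{idealized monomer/dimer.}
#'   \item{oh_radical, ch3_radical, ch2_triplet}{small radicals/diradical.}
#'   \item{ethane, propyl_radical}{alkane and 1-propyl radical.}
#'   \item{pentenyl_radical, pentene}{pent-4-en-1-yl radical and
#'     pent-1-ene (chain-polymerization analog pair).}
#'   \item{ester_radical}{methyl-ester carbon radical (acrylate-chain
#'     analog).}
#'   \item{ethanethiol, ethylthiyl}{CH3CH2SH and its thiyl radical
#'     (thiol hydrogen-abstraction analog).}
#'   \item{imidazolylidene}{N-heterocyclic carbene ring (singlet by
#'     default; pass `multiplicity = 3` for the triplet).}
#' }
#'
#' @param name fixture name.
#' @param d He-dimer separation (Angstrom).
#' @param multiplicity override for fixtures with several spin states.
#' @param active_atoms optional active set stored on the molecule.
#' @return a [molecule()].
#' @export
fixture <- function(name, d = 3.0, multiplicity = NULL,
                    active_atoms = integer(0)) {
  rCH <- 1.09; rCC <- 1.53
  m <- switch(name,
    h2 = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0))),
    h2_stretched = molecule(c("H", "H"), rbind(c(0, 0, 0), c(1.50, 0, 0))),
    he_dimer = molecule(c("He", "He"), rbind(c(0, 0, 0), c(d, 0, 0))),
    h_atom = molecule("H", matrix(0, 1, 3), multiplicity = 2L),
    water = molecule(c("O", "H", "H"),
                     .zbuild(list(c(1, NA, NA, 0.96, 0, 0),
                                  c(1, 2, NA, 0.96, 104.5, 0)))),
    water_dimer = {
      zm <- list(c(1, NA, NA, 0.96, 0, 0),          # H2 (donor H)
                 c(1, 2, NA, 0.96, 104.5, 0),       # H3
                 c(2, 1, 3, 1.95, 175, 120),        # O4 acceptor
                 c(4, 2, 1, 0.96, 110, 120),        # H5
                 c(4, 2, 1, 0.96, 110, -120))       # H6
      molecule(c("O", "H", "H", "O", "H", "H"), .zbuild(zm))
    },
    oh_radical = molecule(c("O", "H"), rbind(c(0, 0, 0), c(0.97, 0, 0)),
                          multiplicity = 2L),
    ch3_radical = {
      zm <- list(c(1, NA, NA, 1.079, 0, 0),
                 c(1, 2, NA, 1.079, 120, 0),
                 c(1, 2, 3, 1.079, 120, 180))
      molecule(c("C", "H", "H", "H"), .zbuild(zm), multiplicity = 2L)
    },
    ch2_triplet = molecule(c("C", "H", "H"),
                           .zbuild(list(c(1, NA, NA, 1.085, 0, 0),
                                        c(1, 2, NA, 1.085, 134, 0))),
                           multiplicity = 3L),
    ethane = {
      zm <- list(c(1, NA, NA, rCC, 0, 0),
                 c(1, 2, NA, rCH, 111, 0),
                 c(1, 2, 3, rCH, 111, 120),
                 c(1, 2, 3, rCH, 111, -120),
                 c(2, 1, 3, rCH, 111, 60),
                 c(2, 1, 3, rCH, 111, 180),
                 c(2, 1, 3, rCH, 111, -60))
      molecule(rep(c("C", "C", "H"), c(1, 1, 6)), .zbuild(zm))
    },
    propyl_radical = {
      zm <- list(c(1, NA, NA, rCC, 0, 0),            # C2
                 c(2, 1, NA, rCC, 112, 0),           # C3 (radical center)
                 c(1, 2, 3, rCH, 111, 60),           # H on C1
                 c(1, 2, 3, rCH, 111, 180),
                 c(1, 2, 3, rCH, 111, -60),
                 c(2, 1, 3, rCH, 109, 120),          # H on C2
                 c(2, 1, 3, rCH, 109, -120),
                 c(3, 2, 1, 1.08, 120, 30),          # H on C3
                 c(3, 2, 1, 1.08, 120, 210))
      molecule(c("C", "C", "C", rep("H", 7)),
               .zbuild(zm), multiplicity = 2L)
    },
    pentenyl_radical = {
      zm <- list(c(1, NA, NA, 1.33, 0, 0),           # C2 = C1 double bond
                 c(2, 1, NA, 1.50, 122, 0),          # C3
                 c(3, 2, 1, rCC, 112, 180),          # C4
                 c(4, 3, 2, rCC, 112, 180),          # C5 radical center
                 c(1, 2, 3, 1.08, 121, 0),           # H2C1
                 c(1, 2, 3, 1.08, 121, 180),
                 c(2, 1, 3, 1.08, 119, 180),         # HC2
                 c(3, 2, 1, rCH, 109, 60),           # H2C3
                 c(3, 2, 1, rCH, 109, -60),
                 c(4, 3, 2, rCH, 109, 60),           # H2C4
                 c(4, 3, 2, rCH, 109, -60),
                 c(5, 4, 3, 1.08, 120, 90),          # H2C5 (radical)
                 c(5, 4, 3, 1.08, 120, -90))
      molecule(rep(c("C", "H"), c(5, 9)), .zbuild(zm), multiplicity = 2L)
    },
    pentene = {
      zm <- list(c(1, NA, NA, 1.33, 0, 0),
                 c(2, 1, NA, 1.50, 122, 0),
                 c(3, 2, 1, rCC, 112, 180),
                 c(4, 3, 2, rCC, 112, 180),
                 c(1, 2, 3, 1.08, 121, 0),
                 c(1, 2, 3, 1.08, 121, 180),
                 c(2, 1, 3, 1.08, 119, 180),
                 c(3, 2, 1, rCH, 109, 60),
                 c(3, 2, 1, rCH, 109, -60),
                 c(4, 3, 2, rCH, 109, 60),
                 c(4, 3, 2, rCH, 109, -60),
                 c(5, 4, 3, rCH, 111, 180),          # CH3
                 c(5, 4, 3, rCH, 111, 60),
                 c(5, 4, 3, rCH, 111, -60))
      molecule(rep(c("C", "H"), c(5, 10)), .zbuild(zm))
    },
    ester_radical = {
      # CH3-O-C(=O)-CH2. : methyl-ester with a radical methylene
      zm <- list(c(1, NA, NA, 1.43, 0, 0),           # O2 (ester O)
                 c(2, 1, NA, 1.36, 116, 0),          # C3 (carbonyl C)
                 c(3, 2, 1, 1.21, 125, 180),         # O4 (=O)
                 c(3, 2, 1, 1.50, 111, 0),           # C5 (radical CH2)
                 c(1, 2, 3, rCH, 110, 60),           # CH3
                 c(1, 2, 3, rCH, 110, 180),
                 c(1, 2, 3, rCH, 110, -60),
                 c(5, 3, 2, 1.08, 120, 30),
                 c(5, 3, 2, 1.08, 120, 210))
      molecule(c("C", "O", "C", "O", "C", "H", "H", "H", "H", "H"),
               .zbuild(zm), multiplicity = 2L)
    },
    ethanethiol = {
      zm <- list(c(1, NA, NA, rCC, 0, 0),            # C2
                 c(2, 1, NA, 1.82, 110, 0),          # S3
                 c(3, 2, 1, 1.34, 96, 180),          # H on S
                 c(1, 2, 3, rCH, 111, 60),
                 c(1, 2, 3, rCH, 111, 180),
                 c(1, 2, 3, rCH, 111, -60),
                 c(2, 1, 3, rCH, 109, 120),
                 c(2, 1, 3, rCH, 109, -120))
      molecule(c("C", "C", "S", "H", "H", "H", "H", "H", "H"), .zbuild(zm))
    },
    ethylthiyl = {
      zm <- list(c(1, NA, NA, rCC, 0, 0),
                 c(2, 1, NA, 1.82, 110, 0),
                 c(1, 2, 3, rCH, 111, 60),
                 c(1, 2, 3, rCH, 111, 180),
                 c(1, 2, 3, rCH, 111, -60),
                 c(2, 1, 3, rCH, 109, 120),
                 c(2, 1, 3, rCH, 109, -120))
      molecule(c("C", "C", "S", "H", "H", "H", "H", "H"), .zbuild(zm),
               multiplicity = 2L)
    },
    imidazolylidene = {
      # planar five-ring N1-C2-N3-C4-C5 with H on N1, N3, C4, C5;
      # C2 is the carbene center
      ang <- (90 + 72 * 0:4) * pi / 180
      ring <- 1.32 / (2 * sin(pi / 5)) * cbind(cos(ang), sin(ang), 0)
      hpos <- 1.0 * ring / (1.32 / (2 * sin(pi / 5))) + ring
      sym <- c("C", "N", "C", "C", "N")
      coords <- rbind(ring, hpos[c(2, 3, 4, 5), ])
      molecule(c(sym, "H", "H", "H", "H"), coords)
    },
    stop("unknown fixture: ", name))
  if (!is.null(multiplicity)) {
    m <- molecule(m$symbols, m$coords, m$charge, multiplicity,
                  active_atoms)
  } else if (length(active_atoms)) {
    m <- molecule(m$symbols, m$coords, m$charge, m$multiplicity,
                  active_atoms)
  }
  m
}

#' Names of all built-in fixtures
#' @return character vector accepted by [fixture()].
#' @export
fixture_catalog <- function() {
  c("h2", "h2_stretched", "he_dimer", "h_atom", "water", "water_dimer",
    "oh_radical", "ch3_radical", "ch2_triplet", "ethane", "propyl_radical",
    "pentenyl_radical", "pentene", "ester_radical", "ethanethiol",
    "ethylthiyl", "imidazolylidene")
}
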