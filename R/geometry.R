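# Internal 3D geometry helpers: torsion placement (NeRF) and side-chain
# construction from the embedded internal-coordinate table.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom X given positions p1, p2, p3 such that |X - p3| = bond,
# angle(p2, p3, X) = ang (deg) and torsion(p1, p2, p3, X) = dih (deg).
# Natural extension reference frame construction.
place_atom <- function(p1, p2, p3, bond, ang, dih) {
  ang <- deg2rad(ang)
  dih <- deg2rad(dih)
  bc <- unit(p3 - p2)
  n <- unit(cross3(p2 - p1, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# Torsion angle p1-p2-p3-p4 in degrees, IUPAC sign convention.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * unit(b2)), sum(n1 * n2)) * 180 / pi
}

# Build side-chain heavy atoms for `restype` on a backbone given as a named
# list of coordinates (N, CA, C). `chis` is a numeric vector of chi angles
# (degrees), possibly length 0. Returns a data.frame name/x/y/z in template
# order, excluding backbone atoms.
build_sidechain <- function(restype, backbone, chis) {
  zm <- zmatrix_table()
  rows <- zm[zm$restype == restype, , drop = FALSE]
  if (nrow(rows) == 0L) {
    if (restype == "GLY") {
      return(data.frame(name = character(), x = numeric(), y = numeric(),
                        z = numeric(), stringsAsFactors = FALSE))
    }
    stop("no side-chain template for residue type '", restype, "'")
  }
  coords <- list(N = backbone$N, CA = backbone$CA, C = backbone$C)
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    for (ref in c(r$p1, r$p2, r$p3)) {
      if (is.null(coords[[ref]])) {
        stop("side-chain reference atom '", ref, "' missing for ", restype)
      }
    }
    dih <- r$offset
    if (r$dih != "fixed") {
      k <- as.integer(sub("chi", "", r$dih))
      if (k > length(chis) || is.na(chis[k])) {
        stop(restype, " needs chi", k, " but rotamer provides ",
             length(chis), " chi angle(s)")
      }
      dih <- chis[k] + r$offset
    }
    coords[[r$atom]] <- place_atom(coords[[r$p1]], coords[[r$p2]],
                                   coords[[r$p3]], r$bond, r$angle, dih)
    out[[i]] <- data.frame(name = r$atom,
                           x = coords[[r$atom]][1],
                           y = coords[[r$atom]][2],
                           z = coords[[r$atom]][3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
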