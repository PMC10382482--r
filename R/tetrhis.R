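# Synthetic reconstruction of a cobalt-dependent polyhistidine
# tetramerisation (TetrHis-like) assembly.  This is NOT deposited
# coordinates: it is a geometric instantiation of the published
# coordination topology — four unique cobalt site classes, twofold-related
# into eight ions, coordinating 3-5 protein residues each from the
# C-terminal sortase/6xHis/Strep region — built so that detection and
# classification code can be exercised without the crystallographic entry.

TETRHIS_SEQ <- c("266" = "LEU", "267" = "PRO", "268" = "GLU",
                 "269" = "THR", "270" = "GLY", "271" = "HIS",
                 "272" = "HIS", "273" = "HIS", "274" = "HIS",
                 "275" = "HIS", "276" = "HIS", "277" = "TRP",
                 "278" = "SER", "279" = "HIS", "280" = "PRO",
                 "281" = "GLN", "282" = "PHE", "283" = "GLU",
                 "284" = "LYS")

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Synthetic TetrHis-like cobalt tetramerisation assembly
#'
#' Builds an idealised four-chain assembly carrying eight cobalt ions in
#' four unique coordination-site classes: a 3-residue trigonal-bipyramidal
#' site completed by two waters, a 4-residue octahedral site with a
#' bidentate glutamate and one water, a 5-residue octahedral site bridging
#' three chains, and a 3-residue trigonal-pyramidal site — with every tag
#' histidine (His271-His276) except His271 of the first chain class
#' engaged in cobalt coordination.  Donor atoms sit exactly on ideal
#' polyhedron vertices at the given bond length; the twofold about z
#' generates the second half of the assembly.
#'
#' This object is synthetic: it reproduces a published coordination
#' *topology* for testing site detection, classification, deduplication
#' and motif scanning, not any deposited atomic coordinates.
#'
#' @param seed Integer seed (random per-site vertex orientations).
#' @param bond_length Metal-donor distance, Angstrom.
#' @return A [structure_model()] with chains `A`, `B`, `W`, `M` and their
#'   twofold copies; cobalt ions are HETATM records with element `CO`.
#' @export
synthetic_tetrhis_assembly <- function(seed = 1L, bond_length = 2.1) {
  with_seed(seed, {
    s <- list(s1 = c(9, 5, 7), s2 = c(15, -4, 2),
              s3 = c(0, 6, -6), s4 = c(10, 9, -9))
    flip <- function(p) c(-p[1], -p[2], p[3])  # the twofold about z
    # ideal vertex directions, randomly oriented per site
    oct <- ideal_geometries(6)$octahedral
    tbp <- ideal_geometries(5)$trigonal_bipyramidal
    tp3 <- ideal_geometries(3)$trigonal_pyramidal
    v1 <- tbp %*% t(random_rotation())
    v2 <- oct %*% t(random_rotation())
    v3 <- oct %*% t(random_rotation())
    v4 <- tp3 %*% t(random_rotation())
    at <- function(site, vrow) site + bond_length * vrow
    # donor atom placements in the inner (pre-twofold) model.
    # chain A feeds sites 1-4 directly; chain B contributes to sites 1-3
    # directly and, via its twofold copy, the cross-chain donors of sites
    # 3 and 4 (placed at the image site so the copy lands on the site).
    donors <- list(
      list("A", 279L, "NE2", at(s$s1, v1[1, ])),
      list("B", 273L, "NE2", at(s$s1, v1[2, ])),
      list("B", 275L, "NE2", at(s$s1, v1[3, ])),
      list("A", 268L, "OE1", at(s$s2, v2[1, ])),  # cis pair of vertices
      list("A", 268L, "OE2", at(s$s2, v2[3, ])),
      list("A", 273L, "NE2", at(s$s2, v2[2, ])),
      list("A", 275L, "NE2", at(s$s2, v2[4, ])),
      list("B", 279L, "NE2", at(s$s2, v2[5, ])),
      list("A", 276L, "NE2", at(s$s3, v3[1, ])),
      list("B", 276L, "NE2", at(s$s3, v3[2, ])),
      list("B", 268L, "OE1", flip(at(s$s3, v3[3, ]))),
      list("B", 268L, "OE2", flip(at(s$s3, v3[5, ]))),
      list("B", 272L, "NE2", flip(at(s$s3, v3[4, ]))),
      list("B", 274L, "NE2", flip(at(s$s3, v3[6, ]))),
      list("A", 272L, "NE2", at(s$s4, v4[1, ])),
      list("A", 274L, "NE2", at(s$s4, v4[2, ])),
      list("B", 271L, "NE2", flip(at(s$s4, v4[3, ]))))
    waters <- rbind(at(s$s1, v1[4, ]), at(s$s1, v1[5, ]),
                    at(s$s2, v2[6, ]))
    site_of_donor <- function(p) {
      # nearest site or image, for pointing the CA outward
      all_sites <- rbind(do.call(rbind, s),
                         do.call(rbind, lapply(s, flip)))
      all_sites[which.min(colSums((t(all_sites) - p)^2)), ]
    }
    rows <- list()
    add_atom <- function(chain, resno, resid, elety, elesy, p,
                         type = "ATOM") {
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, eleno = 0L, elety = elety, resid = resid,
        chain = chain, resno = resno, insert = "",
        x = p[1], y = p[2], z = p[3], o = 1, b = 0, elesy = elesy,
        stringsAsFactors = FALSE)
    }
    for (ch in c("A", "B")) {
      base_y <- if (ch == "A") 22 else -22
      for (rn in as.integer(names(TETRHIS_SEQ))) {
        resid <- TETRHIS_SEQ[[as.character(rn)]]
        mine <- Filter(function(d) d[[1]] == ch && d[[2]] == rn, donors)
        if (length(mine)) {
          ctr <- colMeans(do.call(rbind, lapply(mine, `[[`, 4)))
          out_dir <- ctr - site_of_donor(ctr)
          out_dir <- out_dir / sqrt(sum(out_dir^2))
          add_atom(ch, rn, resid, "CA", "C", ctr + 4 * out_dir)
          for (d in mine) {
            add_atom(ch, rn, resid, d[[3]],
                     substr(d[[3]], 1, 1), d[[4]])
          }
        } else {
          add_atom(ch, rn, resid, "CA", "C",
                   c(3.5 * (rn - 266) - 20, base_y, 14))
        }
      }
    }
    for (wi in seq_len(nrow(waters))) {
      add_atom("W", wi, "HOH", "O", "O", waters[wi, ], type = "HETATM")
    }
    for (si in seq_along(s)) {
      add_atom("M", si, "CO", "CO", "CO", s[[si]], type = "HETATM")
    }
    inner <- structure_model(do.call(rbind, rows))
    build_assembly(inner, list(rigid_transform(),
                               rigid_transform(rotation_z(pi))))
  })
}
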