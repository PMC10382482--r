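# Structure-derived quantifications: metal coordination sites and their
# geometry, interface buried area (Shrake-Rupley SASA), interface hydrogen
# bonds, and polyhistidine-motif scanning.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90, CO = 1.30, NI = 1.30, ZN = 1.39, CU = 1.40,
               FE = 1.30, MN = 1.40, MG = 1.73, CA = 1.75, "NA" = 2.27,
               CL = 1.75, CD = 1.55)
DEFAULT_VDW <- 1.70
WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")
METAL_ELEMENTS <- c("CO", "NI", "ZN", "CU", "FE", "CD", "MN", "MG")

vdw_radius <- function(elesy) {
  r <- VDW_RADII[toupper(elesy)]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

# All permutations of 1..n (n <= 7 in practice).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

# Ideal coordination polyhedra as unit vertex directions.
ideal_geometries <- function(cn) {
  tet3 <- rbind(c(2 * sqrt(2) / 3, 0, -1 / 3),
                c(-sqrt(2) / 3, sqrt(2 / 3), -1 / 3),
                c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
  switch(as.character(cn),
    "3" = list(trigonal_pyramidal = tet3,
               trigonal_planar = rbind(c(1, 0, 0),
                                       c(-0.5, sqrt(3) / 2, 0),
                                       c(-0.5, -sqrt(3) / 2, 0))),
    "5" = list(trigonal_bipyramidal = rbind(c(0, 0, 1), c(0, 0, -1),
                                            c(1, 0, 0),
                                            c(-0.5, sqrt(3) / 2, 0),
                                            c(-0.5, -sqrt(3) / 2, 0)),
               square_pyramidal = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                                        c(-1, 0, 0), c(0, -1, 0))),
    "6" = list(octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))),
    list())
}

# Angle matrix (degrees) between rows of a direction matrix; pmin/pmax
# would drop dims, so the clamped acos is written back in place.
angle_matrix <- function(dirs) {
  g <- tcrossprod(dirs / sqrt(rowSums(dirs^2)))
  g[] <- acos(pmin(1, pmax(-1, as.numeric(g)))) * 180 / pi
  g
}

#' Classify the coordination geometry of a metal site
#'
#' Compares the observed donor-metal-donor angle set against ideal
#' polyhedra of the same coordination number under the optimal assignment
#' of donors to ideal vertices (exhaustive over permutations, exact for
#' coordination numbers up to 7) and labels the site by the best-matching
#' polyhedron, or `"other"` when the best angle RMSD exceeds `max_rmsd`
#' degrees, the coordination number has no named ideal, or fewer than 3
#' donors are present.
#'
#' @param site A `metal_site` (from [find_metal_sites()]) or a list with
#'   `metal_pos` (length-3) and `donor_pos` (n x 3 matrix).
#' @param max_rmsd Acceptance threshold in degrees.
#' @return list with `label` (`trigonal_pyramidal`, `trigonal_bipyramidal`,
#'   `octahedral` or `other`), `angle_rmsd` (degrees) and `reason` for
#'   `other` calls.
#' @export
classify_geometry <- function(site, max_rmsd = 25) {
  dirs <- sweep(site$donor_pos, 2, site$metal_pos)
  n <- nrow(dirs)
  if (n < 3L) {
    return(list(label = "other", angle_rmsd = NA_real_,
                reason = "fewer than 3 ligands"))
  }
  ideals <- ideal_geometries(n)
  if (!length(ideals)) {
    return(list(label = "other", angle_rmsd = NA_real_,
                reason = sprintf("no named ideal for CN %d", n)))
  }
  obs_ang <- angle_matrix(dirs)
  perms <- permutations(n)
  ut <- upper.tri(obs_ang)
  best <- list(label = "other", angle_rmsd = Inf)
  for (nm in names(ideals)) {
    ideal_ang <- angle_matrix(ideals[[nm]])
    for (p in seq_len(nrow(perms))) {
      perm <- perms[p, ]
      d <- obs_ang[ut] - ideal_ang[perm, perm][ut]
      rmsd <- sqrt(mean(d^2))
      if (rmsd < best$angle_rmsd) best <- list(label = nm, angle_rmsd = rmsd)
    }
  }
  if (best$angle_rmsd > max_rmsd ||
      !best$label %in% c("trigonal_pyramidal", "trigonal_bipyramidal",
                         "octahedral")) {
    return(list(label = "other", angle_rmsd = best$angle_rmsd,
                reason = sprintf("best match %s (RMSD %.1f deg)",
                                 best$label, best$angle_rmsd)))
  }
  list(label = best$label, angle_rmsd = best$angle_rmsd, reason = NULL)
}

#' Detect metal coordination sites
#'
#' For every metal ion in the model, collects the N/O/S donor atoms within
#' the coordination cutoff, counts coordinating protein residues and waters
#' separately, classifies the coordination geometry and groups sites into
#' unique classes by their sorted (residue-name, atom-name) donor
#' signatures.
#'
#' @param model A [structure_model()] (may contain waters and hetero
#'   groups).
#' @param metals Element symbols treated as metals.
#' @param cutoff Donor distance cutoff, Angstrom (typical first-shell
#'   metal-donor bonds are ~2.0-2.3 Angstrom).
#' @return list of `metal_site` objects (possibly empty), each with
#'   `metal`, `chain`, `resno`, `metal_pos`, `donors` (data.frame),
#'   `donor_pos`, `n_protein_residues`, `n_waters`, `signature`,
#'   `geometry`, `class_id`; the vector of unique signatures is attached
#'   as attribute `classes`.
#' @export
find_metal_sites <- function(model, metals = METAL_ELEMENTS, cutoff = 2.8) {
  a <- model$atoms
  xyz <- model_coords(model)
  is_metal <- toupper(a$elesy) %in% toupper(metals)
  if (!any(is_metal)) {
    out <- list()
    attr(out, "classes") <- character()
    return(out)
  }
  donor_ok <- toupper(a$elesy) %in% c("N", "O", "S") & !is_metal
  sites <- lapply(which(is_metal), function(mi) {
    mpos <- xyz[mi, ]
    d <- sqrt(colSums((t(xyz) - mpos)^2))
    sel <- which(donor_ok & d <= cutoff & d > 1e-6)
    donors <- data.frame(atom = a$elety[sel], resid = a$resid[sel],
                         resno = a$resno[sel], chain = a$chain[sel],
                         elesy = a$elesy[sel], distance = d[sel],
                         stringsAsFactors = FALSE)
    is_w <- donors$resid %in% WATER_RESIDS
    sig <- paste(sort(paste(donors$resid, donors$atom)), collapse = "|")
    site <- list(metal = a$elesy[mi], chain = a$chain[mi],
                 resno = a$resno[mi], metal_pos = mpos,
                 donors = donors,
                 donor_pos = xyz[sel, , drop = FALSE],
                 n_protein_residues = length(unique(
                   paste(donors$chain, donors$resno)[!is_w])),
                 n_waters = sum(is_w), signature = sig)
    site$geometry <- if (nrow(donors) >= 3L) {
      classify_geometry(site)
    } else {
      list(label = "other", angle_rmsd = NA_real_,
           reason = "fewer than 3 ligands")
    }
    class(site) <- "metal_site"
    site
  })
  classes <- unique(vapply(sites, `[[`, character(1), "signature"))
  for (i in seq_along(sites)) {
    sites[[i]]$class_id <- match(sites[[i]]$signature, classes)
  }
  attr(sites, "classes") <- classes
  sites
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the sphere-point method: each atom's solvent sphere
#' (van der Waals radius + probe) is sampled on a deterministic Fibonacci
#' lattice and points buried inside any neighbour's sphere are removed.
#'
#' @param model A [structure_model()] or an atom data.frame.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom (>= 960 for production use).
#' @return Numeric vector of per-atom areas, Angstrom^2.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960L) {
  a <- if (inherits(model, "structure_model")) model$atoms else model
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$elesy) + probe
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)
  out <- numeric(n)
  maxr <- max(radii)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < radii[i] + radii[nb]]
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- colSums((t(pts[free, , drop = FALSE]) - xyz[j, ])^2)
        free[free] <- dj2 >= radii[j]^2
      }
      out[i] <- sum(free) / n_points * 4 * pi * radii[i]^2
    } else {
      out[i] <- 4 * pi * radii[i]^2
    }
  }
  out
}

# Resolve a selection (chain vector, or list(chain=, resno=range)) to rows.
select_atoms <- function(model, sel) {
  a <- model$atoms
  if (is.character(sel)) return(which(a$chain %in% sel))
  if (is.list(sel)) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
    if (!is.null(sel$resno)) {
      keep <- keep & a$resno >= min(sel$resno) & a$resno <= max(sel$resno)
    }
    return(which(keep))
  }
  stop("selection must be a chain vector or list(chain=, resno=)",
       call. = FALSE)
}

#' Buried interface area between two selections
#'
#' `(SASA(A) + SASA(B) - SASA(AB)) / 2`, the per-side buried area, by
#' [shrake_rupley_sasa()].
#'
#' @param model A [structure_model()].
#' @param selA,selB Selections: chain id vectors or
#'   `list(chain =, resno = c(from, to))`.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom.
#' @return Buried area, Angstrom^2.
#' @export
interface_area <- function(model, selA, selB, probe = 1.4,
                           n_points = 960L) {
  ia <- select_atoms(model, selA)
  ib <- select_atoms(model, selB)
  if (!length(ia) || !length(ib)) {
    stop("empty interface selection", call. = FALSE)
  }
  if (length(intersect(ia, ib))) {
    stop("interface selections overlap", call. = FALSE)
  }
  a <- model$atoms
  sA <- sum(shrake_rupley_sasa(a[ia, ], probe, n_points))
  sB <- sum(shrake_rupley_sasa(a[ib, ], probe, n_points))
  sAB <- sum(shrake_rupley_sasa(a[c(ia, ib), ], probe, n_points))
  (sA + sB - sAB) / 2
}

# Donor/acceptor templates for the 20 standard residues.
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH",
  CYS = "SG")
SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Hydrogen-bond criteria
#'
#' @param da_max Maximum donor-acceptor distance, Angstrom.
#' @param dha_min Minimum D-H...A angle (degrees) where the donor hydrogen
#'   can be placed from ideal geometry (backbone amides); donors without a
#'   placeable hydrogen are accepted on distance alone.
#' @param use_angle Apply the angle criterion at all.
#' @return list of criteria (echoed in the output).
#' @export
hbond_criteria <- function(da_max = 3.5, dha_min = 120, use_angle = TRUE) {
  list(da_max = da_max, dha_min = dha_min, use_angle = use_angle)
}

# Ideal backbone amide hydrogen: in the C(prev)-N-CA plane, opposite the
# bisector of the two bonds, 1.0 A from N.
place_amide_h <- function(n_pos, c_prev, ca_pos) {
  u1 <- (n_pos - c_prev) / sqrt(sum((n_pos - c_prev)^2))
  u2 <- (n_pos - ca_pos) / sqrt(sum((n_pos - ca_pos)^2))
  h <- u1 + u2
  nh <- sqrt(sum(h^2))
  if (nh < 1e-6) return(NULL)
  n_pos + h / nh
}

#' Interface hydrogen bonds
#'
#' Donor-acceptor pairs across two selections with D-A distance at most
#' `da_max`; when the donor is a backbone amide whose hydrogen is placeable
#' from ideal geometry, the D-H...A angle must also reach `dha_min`.
#' Donors/acceptors come from residue templates; unknown residue types are
#' skipped with a warning.  Both directions (A donates to B and B to A)
#' are searched.
#'
#' @param model A [structure_model()].
#' @param selA,selB Selections as in [interface_area()].
#' @param criteria A [hbond_criteria()].
#' @return data.frame of bonds (donor/acceptor chain, resno, resid, atom,
#'   distance, angle) with the criteria attached as attribute `criteria`.
#' @export
hydrogen_bonds <- function(model, selA, selB, criteria = hbond_criteria()) {
  a <- model$atoms
  ia <- select_atoms(model, selA)
  ib <- select_atoms(model, selB)
  unknown <- setdiff(unique(a$resid[c(ia, ib)]),
                     c(STANDARD_RESIDUES, WATER_RESIDS))
  if (length(unknown)) {
    warning("skipping unknown residue type(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  polar_atoms <- function(idx, role) {
    rows <- lapply(idx, function(i) {
      resid <- a$resid[i]
      if (!resid %in% STANDARD_RESIDUES) return(NULL)
      at <- a$elety[i]
      tmpl <- if (role == "donor") SIDECHAIN_DONORS else SIDECHAIN_ACCEPTORS
      is_bb <- if (role == "donor") {
        at == "N" && resid != "PRO"
      } else {
        at %in% c("O", "OXT")
      }
      is_sc <- at %in% (tmpl[[resid]] %||% character())
      if (!is_bb && !is_sc) return(NULL)
      data.frame(i = i, backbone = is_bb)
    })
    do.call(rbind, rows)
  }
  xyz <- model_coords(model)
  find_pairs <- function(di, ai_) {
    don <- polar_atoms(di, "donor"); acc <- polar_atoms(ai_, "acceptor")
    if (is.null(don) || is.null(acc)) return(NULL)
    out <- list()
    for (r in seq_len(nrow(don))) {
      i <- don$i[r]
      d <- sqrt(colSums((t(xyz[acc$i, , drop = FALSE]) - xyz[i, ])^2))
      hits <- which(d <= criteria$da_max)
      for (h in hits) {
        j <- acc$i[h]
        angle <- NA_real_
        if (criteria$use_angle && don$backbone[r]) {
          # locate C of the previous residue (same chain) and own CA
          same_res <- a$chain == a$chain[i] & a$resno == a$resno[i] &
            a$insert == a$insert[i]
          prev_res <- a$chain == a$chain[i] & a$resno == a$resno[i] - 1L
          ca <- which(same_res & a$elety == "CA")
          cp <- which(prev_res & a$elety == "C")
          if (length(ca) == 1L && length(cp) == 1L) {
            hp <- place_amide_h(xyz[i, ], xyz[cp, ], xyz[ca, ])
            if (!is.null(hp)) {
              v1 <- xyz[i, ] - hp; v2 <- xyz[j, ] - hp
              angle <- acos(pmin(1, pmax(-1,
                sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
              if (angle < criteria$dha_min) next
            }
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = a$chain[i], donor_resno = a$resno[i],
          donor_resid = a$resid[i], donor_atom = a$elety[i],
          acceptor_chain = a$chain[j], acceptor_resno = a$resno[j],
          acceptor_resid = a$resid[j], acceptor_atom = a$elety[j],
          distance = d[h], angle = angle, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  bonds <- rbind(find_pairs(ia, ib), find_pairs(ib, ia))
  if (is.null(bonds)) {
    bonds <- data.frame(donor_chain = character(), donor_resno = integer(),
                        donor_resid = character(), donor_atom = character(),
                        acceptor_chain = character(),
                        acceptor_resno = integer(),
                        acceptor_resid = character(),
                        acceptor_atom = character(), distance = numeric(),
                        angle = numeric(), stringsAsFactors = FALSE)
  }
  attr(bonds, "criteria") <- criteria
  bonds
}

#' Scan for polyhistidine metal-binding motifs
#'
#' Finds maximal runs of at least `min_run` consecutive histidines (author
#' numbering; gaps in the modelled sequence break runs), records which run
#' histidines contact a metal within the coordination cutoff, and
#' classifies each run's motif: `linear` when all protein residues
#' coordinating the attached metals lie within a sequence window of
#' `linear_window` residues (possibly across chains), else
#' `three_dimensional`; runs without metal contacts are `apo`.
#'
#' @param model A [structure_model()].
#' @param min_run Minimum histidine run length.
#' @param cutoff Metal coordination cutoff, Angstrom.
#' @param linear_window Sequence window (residues) defining a linear motif.
#' @param metals Metal element symbols.
#' @return data.frame: chain, run_start, run_length, metal_contacts
#'   (number of run histidines contacting a metal), n_metals, motif_class;
#'   per-histidine contact flags as attribute `his_contacts`.
#' @export
his_motif_scan <- function(model, min_run = 4L, cutoff = 2.8,
                           linear_window = 10L, metals = METAL_ELEMENTS) {
  a <- model$atoms
  xyz <- model_coords(model)
  sites <- find_metal_sites(model, metals, cutoff)
  runs <- list()
  his_rows <- list()
  for (ch in model_chains(model)) {
    in_ch <- a$chain == ch
    res <- unique(a$resno[in_ch & a$resid == "HIS"])
    if (!length(res)) next
    res <- sort(res)
    breaks <- c(0L, which(diff(res) != 1L), length(res))
    for (k in seq_len(length(breaks) - 1L)) {
      seg <- res[(breaks[k] + 1L):breaks[k + 1L]]
      if (length(seg) < min_run) next
      # metal contacts of each run histidine via its side-chain N atoms
      metal_idx <- which(toupper(a$elesy) %in% toupper(metals))
      contact <- vapply(seg, function(rn) {
        sel <- which(in_ch & a$resno == rn &
                       (a$elety %in% c("ND1", "NE2") |
                          !any(a$elety[in_ch & a$resno == rn] %in%
                                 c("ND1", "NE2"))))
        if (!length(sel) || !length(metal_idx)) return(FALSE)
        dmin <- min(vapply(sel, function(i) {
          min(sqrt(colSums((t(xyz[metal_idx, , drop = FALSE]) - xyz[i, ])^2)))
        }, numeric(1)))
        dmin <= cutoff
      }, logical(1))
      # metals attached to this run
      attached <- which(vapply(sites, function(s) {
        any(s$donors$chain == ch & s$donors$resno %in% seg)
      }, logical(1)))
      motif_class <- "apo"
      if (length(attached)) {
        coord_resno <- unlist(lapply(sites[attached], function(s) {
          s$donors$resno[!s$donors$resid %in% WATER_RESIDS]
        }))
        span <- max(coord_resno) - min(coord_resno) + 1L
        motif_class <- if (span <= linear_window) "linear" else
          "three_dimensional"
      }
      runs[[length(runs) + 1L]] <- data.frame(
        chain = ch, run_start = seg[1], run_length = length(seg),
        metal_contacts = sum(contact), n_metals = length(attached),
        motif_class = motif_class, stringsAsFactors = FALSE)
      his_rows[[length(his_rows) + 1L]] <- data.frame(
        chain = ch, resno = seg, contact = contact,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(runs)) do.call(rbind, runs) else
    data.frame(chain = character(), run_start = integer(),
               run_length = integer(), metal_contacts = integer(),
               n_metals = integer(), motif_class = character(),
               stringsAsFactors = FALSE)
  attr(out, "his_contacts") <- if (length(his_rows)) {
    do.call(rbind, his_rows)
  } else {
    NULL
  }
  out
}
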