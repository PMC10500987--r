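# Constrained GROMACS .top dialect: a single molecule block with atoms,
# harmonic bonds (funct 1), Morse bonds (funct 3), tabulated bonds
# (funct 9), pairs, exclusions, harmonic angles (funct 1), periodic proper
# dihedrals (funct 1), plus one documented extension section
# [ soft_repulsion ] used only in state-description files.  Full GROMACS
# grammar (macros, #include, virtual sites, ...) is rejected loudly.
#
# Files use GROMACS units (nm, kJ/mol, degrees); in memory everything is
# Angstrom / kcal/mol / degrees.

.fmt <- function(x) sprintf("%.12g", x)

#' Single-state topology description
#'
#' The reactant- or product-state bonded description of the reacting
#' fragment, in internal units (Angstrom, kcal/mol, degrees).  Atom indices
#' are 1-based within the molecule block.
#'
#' @param atoms Tibble with `name`, `type`, `charge`.
#' @param bonds Harmonic bonds: tibble `i`, `j`, `b0` (A), `k`
#'   (kcal mol-1 A-2).
#' @param morse_bonds Morse bonds (breaking/forming): tibble `i`, `j`, `D`
#'   (kcal/mol), `a` (1/A), `r_eq` (A).
#' @param soft_pairs Soft exponential repulsions replacing 6-12 terms for
#'   atoms whose bonding changes: tibble `i`, `j`, `C` (kcal/mol),
#'   `beta_rep` (1/A).
#' @param angles Tibble `i`, `j`, `k`, `theta0` (deg), `k_theta`
#'   (kcal mol-1 rad-2).
#' @param dihedrals Periodic proper dihedrals: tibble `i`, `j`, `k`, `l`,
#'   `phi0` (deg), `k_phi` (kcal/mol), `mult`.
#' @param pairs 1-4 pair list: tibble `i`, `j`.
#' @param exclusions Tibble `i`, `j`.
#' @param name Molecule name.
#' @param nrexcl GROMACS exclusion generation depth.
#' @return A `topology_subset` object.
#' @export
topology_subset <- function(atoms, bonds = NULL, morse_bonds = NULL,
                            soft_pairs = NULL, angles = NULL,
                            dihedrals = NULL, pairs = NULL,
                            exclusions = NULL, name = "MOL", nrexcl = 3L) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "type", "charge") %in% names(atoms)))
  n <- nrow(atoms)
  chk_idx <- function(tbl, cols, what, idx = c("i", "j")) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    if (is.null(tbl) || (is.data.frame(tbl) && nrow(tbl) == 0)) return(empty)
    stopifnot(is.data.frame(tbl))
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      rlang::abort(sprintf("%s lacks column(s) %s", what,
                           paste(miss, collapse = ", ")),
                   class = "evbfep_domain_error")
    }
    for (cc in idx) {
      v <- tbl[[cc]]
      if (any(v < 1 | v > n | v != as.integer(v))) {
        rlang::abort(sprintf("%s has atom indices outside 1..%d", what, n),
                     class = "evbfep_domain_error")
      }
    }
    tibble::as_tibble(tbl[, cols])
  }
  structure(list(
    name = name, nrexcl = as.integer(nrexcl),
    atoms = tibble::as_tibble(atoms[, c("name", "type", "charge")]),
    bonds = chk_idx(bonds, c("i", "j", "b0", "k"), "bonds"),
    morse_bonds = chk_idx(morse_bonds, c("i", "j", "D", "a", "r_eq"),
                          "morse_bonds"),
    soft_pairs = chk_idx(soft_pairs, c("i", "j", "C", "beta_rep"),
                         "soft_pairs"),
    angles = chk_idx(angles, c("i", "j", "k", "theta0", "k_theta"),
                     "angles", idx = c("i", "j", "k")),
    dihedrals = chk_idx(dihedrals,
                        c("i", "j", "k", "l", "phi0", "k_phi", "mult"),
                        "dihedrals", idx = c("i", "j", "k", "l")),
    pairs = chk_idx(pairs, c("i", "j"), "pairs"),
    exclusions = chk_idx(exclusions, c("i", "j"), "exclusions")
  ), class = "topology_subset")
}

.sort_ij <- function(tbl) {
  if (!nrow(tbl)) return(tbl)
  keys <- tbl[intersect(c("i", "j", "k", "l"), names(tbl))]
  tbl[do.call(order, unname(as.list(keys))), ]
}

#' Write a topology in the constrained GROMACS dialect
#'
#' Deterministic, byte-stable output: fixed ordering and `%.12g` number
#' formatting.  File units are GROMACS (nm, kJ/mol); soft-repulsion pairs go
#' into a documented `[ soft_repulsion ]` extension section (state files
#' only — emitted per-window topologies carry them as tabulated bonds).
#'
#' @param top A [topology_subset()].
#' @param path Output file.
#' @param tabulated Optional tibble `i`, `j`, `table_id`, `scale` of
#'   tabulated (funct 9) bonds to emit instead of / besides explicit
#'   Morse/soft entries.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path, tabulated = NULL) {
  stopifnot(inherits(top, "topology_subset"))
  ln <- c("; evbfep constrained topology dialect",
          "; units: nm, kJ/mol, deg; funct 1 harmonic bond/angle,",
          ";        funct 3 Morse, funct 9 tabulated, dihedrals periodic",
          "",
          "[ moleculetype ]",
          sprintf("%s %d", top$name, top$nrexcl),
          "",
          "[ atoms ]")
  at <- top$atoms
  ln <- c(ln, sprintf("%d %s 1 MOL %s %d %s", seq_len(nrow(at)), at$type,
                      at$name, seq_len(nrow(at)), .fmt(at$charge)))
  bond_lines <- character()
  b <- .sort_ij(top$bonds)
  if (nrow(b)) {
    bond_lines <- c(bond_lines,
                    sprintf("%d %d 1 %s %s", b$i, b$j, .fmt(b$b0 / 10),
                            .fmt(b$k * KCAL_TO_KJ * 100)))
  }
  m <- .sort_ij(top$morse_bonds)
  if (nrow(m)) {
    bond_lines <- c(bond_lines,
                    sprintf("%d %d 3 %s %s %s", m$i, m$j, .fmt(m$r_eq / 10),
                            .fmt(m$D * KCAL_TO_KJ), .fmt(m$a * 10)))
  }
  if (!is.null(tabulated) && nrow(tabulated)) {
    tb <- tabulated[order(tabulated$i, tabulated$j), ]
    bond_lines <- c(bond_lines,
                    sprintf("%d %d 9 %d %s", tb$i, tb$j,
                            as.integer(tb$table_id), .fmt(tb$scale)))
  }
  if (length(bond_lines)) ln <- c(ln, "", "[ bonds ]", bond_lines)
  s <- .sort_ij(top$soft_pairs)
  if (nrow(s)) {
    ln <- c(ln, "", "[ soft_repulsion ]",
            sprintf("%d %d %s %s", s$i, s$j, .fmt(s$C * KCAL_TO_KJ),
                    .fmt(s$beta_rep * 10)))
  }
  p <- .sort_ij(top$pairs)
  if (nrow(p)) ln <- c(ln, "", "[ pairs ]", sprintf("%d %d 1", p$i, p$j))
  e <- .sort_ij(top$exclusions)
  if (nrow(e)) ln <- c(ln, "", "[ exclusions ]", sprintf("%d %d", e$i, e$j))
  a <- .sort_ij(top$angles)
  if (nrow(a)) {
    ln <- c(ln, "", "[ angles ]",
            sprintf("%d %d %d 1 %s %s", a$i, a$j, a$k, .fmt(a$theta0),
                    .fmt(a$k_theta * KCAL_TO_KJ)))
  }
  d <- top$dihedrals
  if (nrow(d)) {
    d <- d[order(d$i, d$j, d$k, d$l), ]
    ln <- c(ln, "", "[ dihedrals ]",
            sprintf("%d %d %d %d 1 %s %s %d", d$i, d$j, d$k, d$l,
                    .fmt(d$phi0), .fmt(d$k_phi * KCAL_TO_KJ),
                    as.integer(d$mult)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a topology written in the constrained dialect
#'
#' Re-parses files produced by [write_topology()] /
#' [write_lambda_topologies()].  Unsupported GROMACS constructs
#' (`#include`, `#define`, unknown sections) raise an error.
#'
#' @param path File to read.
#' @return A list: a [topology_subset()] plus a `tabulated` tibble
#'   (`i`, `j`, `table_id`, `scale`) for funct-9 bonds.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  if (any(grepl("^#", lines))) {
    rlang::abort("preprocessor directives are not part of this dialect",
                 class = "evbfep_io_error")
  }
  lines <- lines[nzchar(lines)]
  sec <- NA_character_
  known <- c("moleculetype", "atoms", "bonds", "soft_repulsion", "pairs",
             "exclusions", "angles", "dihedrals")
  acc <- stats::setNames(rep(list(list()), length(known)), known)
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- trimws(gsub("[][]", "", ln))
      if (!sec %in% known) {
        rlang::abort(sprintf("unsupported section [ %s ]", sec),
                     class = "evbfep_io_error")
      }
      next
    }
    if (is.na(sec)) {
      rlang::abort("content before the first section",
                   class = "evbfep_io_error")
    }
    acc[[sec]] <- c(acc[[sec]], list(strsplit(ln, "\\s+")[[1]]))
  }
  num <- function(x) as.numeric(x)
  mt <- acc$moleculetype[[1]]
  atoms <- purrr::map_dfr(acc$atoms, function(f) {
    tibble::tibble(name = f[5], type = f[2], charge = num(f[7]))
  })
  bonds <- morse <- tab <- NULL
  for (f in acc$bonds) {
    funct <- as.integer(f[3])
    row <- switch(as.character(funct),
      "1" = tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                           b0 = num(f[4]) * 10,
                           k = num(f[5]) / KCAL_TO_KJ / 100),
      "3" = tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                           r_eq = num(f[4]) * 10,
                           D = num(f[5]) / KCAL_TO_KJ, a = num(f[6]) / 10),
      "9" = tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                           table_id = as.integer(f[4]), scale = num(f[5])),
      rlang::abort(sprintf("unsupported bond funct %d", funct),
                   class = "evbfep_io_error"))
    if (funct == 1) bonds <- dplyr::bind_rows(bonds, row)
    if (funct == 3) morse <- dplyr::bind_rows(morse, row)
    if (funct == 9) tab <- dplyr::bind_rows(tab, row)
  }
  soft <- purrr::map_dfr(acc$soft_repulsion, function(f) {
    tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                   C = num(f[3]) / KCAL_TO_KJ, beta_rep = num(f[4]) / 10)
  })
  pairs <- purrr::map_dfr(acc$pairs, function(f) {
    tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]))
  })
  excl <- purrr::map_dfr(acc$exclusions, function(f) {
    tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]))
  })
  angles <- purrr::map_dfr(acc$angles, function(f) {
    tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                   k = as.integer(f[3]), theta0 = num(f[5]),
                   k_theta = num(f[6]) / KCAL_TO_KJ)
  })
  dihed <- purrr::map_dfr(acc$dihedrals, function(f) {
    tibble::tibble(i = as.integer(f[1]), j = as.integer(f[2]),
                   k = as.integer(f[3]), l = as.integer(f[4]),
                   phi0 = num(f[6]), k_phi = num(f[7]) / KCAL_TO_KJ,
                   mult = as.integer(f[8]))
  })
  top <- topology_subset(
    atoms = atoms,
    bonds = if (!is.null(bonds) && nrow(bonds)) bonds[, c("i", "j", "b0", "k")],
    morse_bonds = if (!is.null(morse) && nrow(morse))
      morse[, c("i", "j", "D", "a", "r_eq")],
    soft_pairs = if (nrow(soft)) soft,
    angles = if (nrow(angles)) angles,
    dihedrals = if (nrow(dihed)) dihed,
    pairs = if (nrow(pairs)) pairs,
    exclusions = if (nrow(excl)) excl,
    name = mt[1], nrexcl = as.integer(mt[2])
  )
  list(topology = top,
       tabulated = if (is.null(tab)) tibble::tibble() else tab)
}

#' Write a GROMACS tabulated-bond file
#'
#' Emits the table layout used by tabulated bonds of type 9: distance (nm),
#' energy (kJ/mol) and minus the energy derivative (kJ mol-1 nm-1), on a
#' uniform grid, with the potential pre-scaled by `scale`.  The potential
#' parameters are in internal units (kcal/mol, Angstrom); the grid is in nm.
#'
#' @param potential A [morse_params()] or [soft_repulsion_params()] object.
#' @param grid `c(r_min, r_max, spacing)` in nm; spacing > 0.  `r_min` must
#'   be > 0 for Morse potentials.
#' @param scale Multiplier in \[0, 1\] (a state's lambda weight); 0 gives
#'   all-zero columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tabulated_bond <- function(potential, grid, scale, path) {
  if (length(grid) != 3 || grid[3] <= 0 || grid[2] <= grid[1]) {
    rlang::abort("`grid` must be c(r_min, r_max, spacing) with spacing > 0",
                 class = "evbfep_domain_error")
  }
  if (scale < 0) {
    rlang::abort("`scale` must be >= 0", class = "evbfep_domain_error")
  }
  r_nm <- seq(grid[1], grid[2], by = grid[3])
  r_a <- r_nm * 10
  if (inherits(potential, "morse_params")) {
    if (grid[1] <= 0) {
      rlang::abort("Morse tables need r_min > 0",
                   class = "evbfep_domain_error")
    }
    u <- exp(-potential$a * (r_a - potential$r_eq))
    e_kcal <- potential$D * (1 - u)^2
    dedr_a <- 2 * potential$D * potential$a * u * (1 - u)
  } else if (inherits(potential, "soft_repulsion_params")) {
    e_kcal <- potential$C * exp(-potential$beta_rep * r_a)
    dedr_a <- -potential$beta_rep * e_kcal
  } else {
    rlang::abort("unsupported potential type", class = "evbfep_domain_error")
  }
  e_kj <- scale * KCAL_TO_KJ * e_kcal
  f_kj_nm <- -scale * KCAL_TO_KJ * 10 * dedr_a
  writeLines(sprintf("%.10e %.10e %.10e", r_nm, e_kj, f_kj_nm), path)
  invisible(path)
}

#' @rdname write_tabulated_bond
#' @export
read_tabulated_bond <- function(path) {
  m <- utils::read.table(path, col.names = c("r", "energy", "force"))
  tibble::as_tibble(m)
}

# interpolate a parameter table present in both states, matched on idx cols
.interp_both <- function(rs_tbl, ps_tbl, idx, pars, lam, what) {
  key <- function(t) do.call(paste, c(t[idx], sep = "-"))
  rk <- key(rs_tbl); pk <- key(ps_tbl)
  both <- intersect(rk, pk)
  out_both <- NULL
  if (length(both)) {
    a <- rs_tbl[match(both, rk), ]
    b <- ps_tbl[match(both, pk), ]
    out_both <- a
    for (pp in pars) out_both[[pp]] <- (1 - lam) * a[[pp]] + lam * b[[pp]]
  }
  only_rs <- rs_tbl[!rk %in% both, , drop = FALSE]
  only_ps <- ps_tbl[!pk %in% both, , drop = FALSE]
  list(both = out_both, only_rs = only_rs, only_ps = only_ps)
}

#' Emit one topology per FEP window
#'
#' For every lambda in the schedule a directory `window_###/` is created
#' containing `topol.top` and the tabulated-bond files it references.
#' Interactions present in both states have their parameters (charges, b0/k,
#' theta0/k_theta, phi0/k_phi) interpolated linearly in lambda, mirroring
#' how MD engines scale individual interaction parameters.  Bonds and soft
#' repulsions present in only one state are emitted as tabulated (funct 9)
#' bonds whose table values are the Morse / soft-repulsion energy pre-scaled
#' by that state's weight (1 - lambda for reactant-only, lambda for
#' product-only), so the bonded part of the mapping potential is realized
#' exactly per window.  Angles/dihedrals present in only one state keep
#' their geometry with the force constant scaled by the state weight.  The
#' lambda = 0 and lambda = 1 topologies reproduce the inputs
#' interaction-for-interaction.
#'
#' @param rs,ps Reactant- and product-state [topology_subset()]s sharing the
#'   atom list (names and types).
#' @param schedule Lambda schedule.
#' @param out_dir Output directory.
#' @param grid Tabulated-bond grid `c(r_min, r_max, spacing)` in nm.
#' @return A manifest tibble: `window`, `lambda`, `path`, `n_tables`,
#'   invisibly.
#' @export
write_lambda_topologies <- function(rs, ps, schedule, out_dir,
                                    grid = c(0.01, 1.5, 0.002)) {
  stopifnot(inherits(rs, "topology_subset"), inherits(ps, "topology_subset"))
  schedule <- validate_schedule(schedule)
  if (!identical(rs$atoms$name, ps$atoms$name) ||
      !identical(rs$atoms$type, ps$atoms$type)) {
    rlang::abort("reactant and product topologies must share the atom list",
                 class = "evbfep_domain_error")
  }
  hk <- function(t) paste(t$i, t$j, sep = "-")
  clash <- intersect(hk(rs$bonds), hk(ps$morse_bonds))
  clash <- c(clash, intersect(hk(ps$bonds), hk(rs$morse_bonds)))
  if (length(clash)) {
    rlang::abort(paste0("bond(s) ", paste(clash, collapse = ", "),
                        " change functional form between states"),
                 class = "evbfep_domain_error")
  }
  one_state_harm <- c(setdiff(hk(rs$bonds), hk(ps$bonds)),
                      setdiff(hk(ps$bonds), hk(rs$bonds)))
  one_state_harm <- setdiff(one_state_harm,
                            c(hk(rs$morse_bonds), hk(ps$morse_bonds)))
  if (length(one_state_harm)) {
    rlang::abort(paste0("harmonic bond(s) ",
                        paste(one_state_harm, collapse = ", "),
                        " exist in only one state; breaking/forming bonds",
                        " must be Morse"),
                 class = "evbfep_domain_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(schedule))
  for (w in seq_along(schedule)) {
    lam <- schedule[w]
    wdir <- file.path(out_dir, sprintf("window_%03d", w))
    dir.create(wdir, showWarnings = FALSE)
    atoms <- rs$atoms
    atoms$charge <- (1 - lam) * rs$atoms$charge + lam * ps$atoms$charge
    bonds <- .interp_both(rs$bonds, ps$bonds, c("i", "j"),
                          c("b0", "k"), lam, "bonds")$both
    morse <- .interp_both(rs$morse_bonds, ps$morse_bonds, c("i", "j"),
                          c("D", "a", "r_eq"), lam, "morse")
    soft <- .interp_both(rs$soft_pairs, ps$soft_pairs, c("i", "j"),
                         c("C", "beta_rep"), lam, "soft")
    ang <- .interp_both(rs$angles, ps$angles, c("i", "j", "k"),
                        c("theta0", "k_theta"), lam, "angles")
    angles <- ang$both
    scale_k <- function(tbl, kcol, wgt) {
      if (is.null(tbl) || !nrow(tbl)) return(NULL)
      tbl[[kcol]] <- tbl[[kcol]] * wgt
      tbl
    }
    angles <- dplyr::bind_rows(angles,
                               scale_k(ang$only_rs, "k_theta", 1 - lam),
                               scale_k(ang$only_ps, "k_theta", lam))
    dih <- .interp_both(rs$dihedrals, ps$dihedrals, c("i", "j", "k", "l"),
                        c("phi0", "k_phi"), lam, "dihedrals")
    dihedrals <- dplyr::bind_rows(dih$both,
                                  scale_k(dih$only_rs, "k_phi", 1 - lam),
                                  scale_k(dih$only_ps, "k_phi", lam))
    # single-state bonded terms -> tabulated bonds pre-scaled by the
    # state weight; Morse bonds present in both states keep funct 3 with
    # interpolated parameters
    tab_specs <- list()
    add_tab <- function(tbl, maker, wgt) {
      if (is.null(tbl) || !nrow(tbl)) return()
      for (rix in seq_len(nrow(tbl))) {
        row <- tbl[rix, ]
        tab_specs[[length(tab_specs) + 1]] <<-
          list(i = row$i, j = row$j, pot = maker(row), scale = wgt)
      }
    }
    add_tab(morse$only_rs,
            function(r) morse_params(r$D, r$a, r$r_eq), 1 - lam)
    add_tab(morse$only_ps,
            function(r) morse_params(r$D, r$a, r$r_eq), lam)
    add_tab(soft$only_rs,
            function(r) soft_repulsion_params(r$C, r$beta_rep), 1 - lam)
    add_tab(soft$only_ps,
            function(r) soft_repulsion_params(r$C, r$beta_rep), lam)
    if (length(tab_specs)) {
      ord <- order(vapply(tab_specs, `[[`, numeric(1), "i"),
                   vapply(tab_specs, `[[`, numeric(1), "j"))
      tab_specs <- tab_specs[ord]
    }
    tab_tbl <- NULL
    for (tid in seq_along(tab_specs)) {
      sp <- tab_specs[[tid]]
      write_tabulated_bond(sp$pot, grid, sp$scale,
                           file.path(wdir, sprintf("table_b%d.xvg", tid)))
      tab_tbl <- dplyr::bind_rows(
        tab_tbl,
        tibble::tibble(i = sp$i, j = sp$j, table_id = tid, scale = sp$scale))
    }
    top <- topology_subset(
      atoms = atoms,
      bonds = bonds,
      morse_bonds = morse$both,
      soft_pairs = NULL,
      angles = angles,
      dihedrals = dihedrals,
      pairs = unique(dplyr::bind_rows(rs$pairs, ps$pairs)),
      exclusions = unique(dplyr::bind_rows(rs$exclusions, ps$exclusions)),
      name = rs$name, nrexcl = rs$nrexcl
    )
    path <- file.path(wdir, "topol.top")
    write_topology(top, path, tabulated = tab_tbl)
    manifest[[w]] <- tibble::tibble(window = w, lambda = lam, path = path,
                                    n_tables = length(tab_specs))
  }
  invisible(dplyr::bind_rows(manifest))
}
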