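# minimal reacting-fragment topologies: donor D, transferring H, acceptor A;
# the D-H Morse bond breaks, the H-A Morse bond forms, the D-A harmonic
# "scaffold" bond and the angle change parameters between states

make_rs_top <- function() {
  topology_subset(
    atoms = tibble::tibble(name = c("D", "H", "A"),
                           type = c("CT", "HO", "OH"),
                           charge = c(0.1, 0.4, -0.5)),
    bonds = tibble::tibble(i = 1L, j = 3L, b0 = 2.5, k = 100),
    morse_bonds = tibble::tibble(i = 1L, j = 2L, D = 100, a = 2, r_eq = 1.0),
    soft_pairs = tibble::tibble(i = 2L, j = 3L, C = 5, beta_rep = 2),
    angles = tibble::tibble(i = 2L, j = 1L, k = 3L, theta0 = 110,
                            k_theta = 50),
    pairs = tibble::tibble(i = 1L, j = 3L),
    exclusions = tibble::tibble(i = c(1L, 2L), j = c(2L, 3L)))
}

make_ps_top <- function() {
  rs <- make_rs_top()
  topology_subset(
    atoms = dplyr::mutate(rs$atoms, charge = c(-0.2, 0.45, -0.25)),
    bonds = tibble::tibble(i = 1L, j = 3L, b0 = 2.6, k = 300),
    morse_bonds = tibble::tibble(i = 2L, j = 3L, D = 110, a = 2.2,
                                 r_eq = 0.97),
    soft_pairs = tibble::tibble(i = 1L, j = 2L, C = 5, beta_rep = 2),
    angles = tibble::tibble(i = 2L, j = 1L, k = 3L, theta0 = 115,
                            k_theta = 80),
    pairs = tibble::tibble(i = 1L, j = 3L),
    exclusions = tibble::tibble(i = c(1L, 2L), j = c(2L, 3L)))
}
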