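# Gasteiger-Marsili PEOE parameters (a, b, c) by element and hybridisation
# class. chi_plus is the electronegativity of the cation, used to normalise
# charge flow out of the donor atom; hydrogen uses the conventional 20.02.
gasteiger_parameters <- function() {
  tab <- tibble::tribble(
    ~class,   ~a,    ~b,    ~c,
    "H",      7.17,  6.24, -0.56,
    "C.sp3",  7.98,  9.18,  1.88,
    "C.sp2",  8.79,  9.32,  1.51,
    "C.sp",  10.39,  9.45,  0.73,
    "N.sp3", 11.54, 10.82,  1.36,
    "N.sp2", 12.87, 11.15,  0.85,
    "N.sp",  15.68, 11.70, -0.27,
    "O.sp3", 14.18, 12.92,  1.39,
    "O.sp2", 17.07, 13.79,  0.47,
    "F",     14.66, 13.85,  2.31,
    "Cl",    11.00,  9.69,  1.35,
    "Br",    10.08,  8.47,  1.16,
    "I",      9.90,  7.96,  0.96,
    "S.sp3", 10.14,  9.13,  1.38,
    "S.sp2", 10.88,  9.49,  1.33,
    "P.sp3",  8.90,  8.24,  0.96
  )
  tab$chi_plus <- ifelse(tab$class == "H", 20.02, tab$a + tab$b + tab$c)
  tab
}

# Assign an atom to a parameter class from its element and bond orders.
gasteiger_class <- function(mol) {
  el <- mol$atoms$element
  n <- length(el)
  max_order <- rep(1, n)
  n_double <- integer(n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    o <- if (b$order[r] == 4) 1.5 else b$order[r]
    for (a in c(b$i[r], b$j[r])) {
      max_order[a] <- max(max_order[a], o)
      if (o == 2) n_double[a] <- n_double[a] + 1L
    }
  }
  hyb <- ifelse(max_order >= 3 | n_double >= 2, "sp",
                ifelse(max_order > 1, "sp2", "sp3"))
  ifelse(el %in% c("H", "F", "Cl", "Br", "I"), el, paste(el, hyb, sep = "."))
}

#' Gasteiger-Marsili partial charges
#'
#' Partial equalization of orbital electronegativities (PEOE): in iteration
#' n, each bond moves charge from its less electronegative end to its more
#' electronegative end, proportional to the electronegativity difference,
#' normalised by the donor's cation electronegativity, and damped by
#' `(1/2)^n`. Electronegativities are the quadratic functions
#' `chi = a + b q + c q^2` of the current charge. The procedure is
#' deterministic, independent of atom ordering, and conserves total formal
#' charge exactly.
#'
#' Parameters cover H, C, N, O, S, P and the halogens — the chemistry of
#' typical aminergic-GPCR ligands; molecules with other elements must come
#' with precomputed charges (e.g. read from SDF tags).
#'
#' @param mol A [molecule()].
#' @param n_iterations Damping iterations; 8 (default) is converged to well
#'   below 1e-3 e.
#' @param formal_charges Optional per-atom formal charges used as the
#'   starting state; defaults to all zero.
#' @return List with `charge` (per-atom, elementary-charge units) and
#'   `iterations_run`.
#' @export
gasteiger_charges <- function(mol, n_iterations = 8, formal_charges = NULL) {
  cls <- gasteiger_class(mol)
  par <- gasteiger_parameters()
  idx <- match(cls, par$class)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("no Gasteiger parameters for atom(s) ",
         paste(sprintf("%d (%s)", bad, cls[bad]), collapse = ", "),
         "; supply precomputed charges instead", call. = FALSE)
  }
  a <- par$a[idx]; b <- par$b[idx]; cc <- par$c[idx]
  chi_plus <- par$chi_plus[idx]
  q <- if (is.null(formal_charges)) numeric(length(cls)) else as.numeric(formal_charges)
  bonds <- mol$bonds
  for (n in seq_len(n_iterations)) {
    damp <- 0.5^n
    chi <- a + b * q + cc * q^2
    dq <- numeric(length(q))
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (chi[i] == chi[j]) next
      donor <- if (chi[i] < chi[j]) i else j
      accept <- if (donor == i) j else i
      flow <- (chi[accept] - chi[donor]) / chi_plus[donor] * damp
      dq[donor] <- dq[donor] + flow
      dq[accept] <- dq[accept] - flow
    }
    q <- q + dq
  }
  list(charge = q, iterations_run = n_iterations)
}

#' Resolve per-atom charges for descriptor work
#'
#' Precedence: `"auto"` (default) uses charges carried by the molecule (e.g.
#' read from an SDF tag) when complete, otherwise computes Gasteiger
#' charges; `"input"` insists on precomputed charges and errors without
#' them; `"gasteiger"` always recomputes.
#'
#' @param mol A [molecule()].
#' @param charge_source `"auto"`, `"input"` or `"gasteiger"`.
#' @return Numeric per-atom charges.
#' @export
resolve_charges <- function(mol, charge_source = c("auto", "input", "gasteiger")) {
  charge_source <- match.arg(charge_source)
  have_input <- !anyNA(mol$atoms$charge)
  if (charge_source == "input") {
    if (!have_input) stop("charge_source = 'input' but molecule '", mol$id,
                          "' carries no charges", call. = FALSE)
    return(mol$atoms$charge)
  }
  if (charge_source == "auto" && have_input) return(mol$atoms$charge)
  gasteiger_charges(mol)$charge
}
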