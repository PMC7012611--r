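#' Circuit architectures and parameter conventions
#'
#' A `circuit_spec` bundles everything that defines a cortical circuit
#' architecture in the strong-coupling (balanced) framework: the ordered set
#' of neuronal populations with their polarities, the dimensionless
#' interaction-strength matrix `J` (uA.ms/cm^2; rows are postsynaptic, columns
#' presynaptic), the feedforward strengths `J0`, the synaptic time constants
#' `tau` (ms; `NA` wherever the corresponding `J` entry is a structural zero),
#' the external-population rate `r0` (Hz), single-neuron constants, finite-size
#' counts, and the optogenetic drive parameters.
#'
#' Unit conventions used throughout the package: time in ms, membrane
#' potential in mV, capacitance in uF/cm^2, leak conductance in mS/cm^2.
#' Interaction strengths `J` are in uA.ms/cm^2 so that, with population rates
#' expressed in Hz, products such as `2 * J0 * r0` and `J %*% r` are currents
#' in nA/cm^2 -- the natural scale of the balance equations. The finite-size
#' simulator converts to uA/cm^2 internally.
#'
#' @param populations character vector of population names, e.g. `c("E","I")`.
#'   The first excitatory population is conventionally named `"E"`.
#' @param polarity named vector of +1 (excitatory) / -1 (inhibitory).
#' @param J nonnegative interaction matrix (post x pre) in uA.ms/cm^2.
#' @param J0 named nonnegative feedforward strengths in uA.ms/cm^2.
#' @param tau synaptic time-constant matrix (ms), `NA` where `J == 0`.
#' @param neuron list with elements `C_M` (uF/cm^2), `g_leak` (named, mS/cm^2),
#'   `V_th` and `V_R` (mV).
#' @param r0 external-population firing rate in Hz (default 5).
#' @param sizes list with `N` (named vector of neuron counts) and `K`
#'   (mean in-degree per presynaptic population).
#' @param opto list with `targets` (populations receiving the optogenetic
#'   drive), `I0` (nA/cm^2) and `Gamma0` (mW/mm^2).
#' @param name optional architecture label.
#'
#' @return An object of class `circuit_spec`.
#' @seealso [load_architecture()], [validate_spec()], [effective_matrix()]
#' @export
circuit_spec <- function(populations, polarity, J, J0, tau, neuron,
                         r0 = 5, sizes = NULL, opto = NULL, name = "custom") {
  pops <- as.character(populations)
  P <- length(pops)
  J <- as_pop_matrix(J, pops, fill = 0)
  tau <- as_pop_matrix(tau, pops, fill = NA_real_)
  J0 <- as_pop_vector(J0, pops, fill = 0)
  polarity <- as_pop_vector(polarity, pops, fill = NA_real_)
  g_leak <- as_pop_vector(neuron$g_leak, pops, fill = NA_real_)
  spec <- structure(
    list(
      name = name,
      populations = pops,
      polarity = polarity,
      J = J, J0 = J0, tau = tau,
      r0 = r0,
      neuron = list(C_M = neuron$C_M, g_leak = g_leak,
                    V_th = neuron$V_th, V_R = neuron$V_R),
      sizes = if (!is.null(sizes)) {
        # serialized configs use the key "counts" ("N" is a YAML boolean)
        list(N = as_pop_vector(sizes$counts %||% sizes$N, pops,
                               fill = NA_real_),
             K = sizes$K)
      },
      opto = opto_spec(
        targets = opto$targets %||% "I",
        I0 = opto$I0 %||% 8, Gamma0 = opto$Gamma0 %||% 0.5
      )
    ),
    class = "circuit_spec"
  )
  diag_tbl <- validate_spec(spec)
  errs <- diag_tbl[diag_tbl$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    abort(paste0(
      "invalid circuit specification:\n",
      paste0("  [", errs$field, "] ", errs$message, collapse = "\n")
    ))
  }
  spec
}

as_pop_matrix <- function(x, pops, fill) {
  P <- length(pops)
  out <- matrix(fill, P, P, dimnames = list(pops, pops))
  if (is.null(x)) return(out)
  if (is.matrix(x)) {
    if (is.null(dimnames(x))) {
      stopifnot(all(dim(x) == P))
      out[, ] <- x
    } else {
      out[rownames(x), colnames(x)] <- x
    }
  } else if (is.list(x)) {
    for (post in names(x)) {
      for (pre in names(x[[post]])) out[post, pre] <- x[[post]][[pre]]
    }
  } else {
    abort("matrix argument must be a matrix or a nested named list")
  }
  out
}

as_pop_vector <- function(x, pops, fill) {
  out <- setNames(rep(fill, length(pops)), pops)
  if (is.null(x)) return(out)
  x <- unlist(x)
  if (is.null(names(x))) {
    stopifnot(length(x) == length(pops))
    out[] <- x
  } else {
    out[names(x)] <- x
  }
  out
}

#' Optogenetic drive specification
#'
#' The light-to-current transduction is modeled as
#' `I_opto = I0 * log(1 + Gamma / Gamma0)` (natural logarithm), a saturating
#' map from laser intensity `Gamma` (mW/mm^2) to an effective constant current
#' (nA/cm^2) injected into the target populations. Changing the logarithm
#' base only rescales `Gamma0`.
#'
#' @param targets populations receiving the drive (default `"I"`, the PV
#'   population).
#' @param I0 current amplitude in nA/cm^2 (default 8).
#' @param Gamma0 intensity scale in mW/mm^2 (default 0.5).
#' @return A list of class `opto_spec`.
#' @export
opto_spec <- function(targets = "I", I0 = 8, Gamma0 = 0.5) {
  stopifnot(I0 > 0, Gamma0 > 0)
  structure(list(targets = targets, I0 = I0, Gamma0 = Gamma0),
            class = "opto_spec")
}

#' Optogenetically induced current
#'
#' Computes `I0 * log(1 + Gamma / Gamma0)` in nA/cm^2. The map is zero at
#' `Gamma = 0` and strictly increasing. When `population` is supplied, the
#' current is returned only if that population is an optogenetic target and
#' zero otherwise.
#'
#' @param Gamma laser intensity (mW/mm^2), vectorized; must be nonnegative.
#' @param opto an [opto_spec()].
#' @param population optional population name.
#' @return Current(s) in nA/cm^2.
#' @examples
#' opto_current(0.5)          # 8 * log(2)
#' opto_current(1.5)          # 8 * log(4)
#' @export
opto_current <- function(Gamma, opto = opto_spec(), population = NULL) {
  if (any(Gamma < 0)) abort("laser intensity must be nonnegative")
  if (!is.null(population) && !(population %in% opto$targets)) {
    return(rep(0, length(Gamma)))
  }
  opto$I0 * log(1 + Gamma / opto$Gamma0)
}

#' Load a built-in or user-supplied circuit architecture
#'
#' Built-in architectures: `"two_pop"` (one excitatory, one inhibitory
#' population), `"two_pop_noEE"` (identical but with the recurrent excitation
#' removed), `"model1_nonparadox"` and `"model1_paradox"` (PC/PV/SOM/VIP
#' circuits with V1-like connectivity in the regimes with and without the
#' paradoxical PV response), and `"model2"` (PC/PV/SOM/X circuit in which the
#' third inhibitory population does not project to SOM neurons). A path to a
#' YAML file, or an already-parsed list with the same schema, is also
#' accepted. Configs may alternatively supply finite-size couplings `j`
#' together with `K`; the loader normalizes them to dimensionless `J`
#' (`J = j * sqrt(K)`).
#'
#' @param name_or_config architecture name, YAML path, or config list.
#' @return A validated [circuit_spec()].
#' @examples
#' spec <- load_architecture("model2")
#' spec$J["S", c("E", "I")]  # SOM receives only PC and PV input
#' @export
load_architecture <- function(name_or_config) {
  if (is.list(name_or_config)) {
    cfg <- name_or_config
  } else if (is.character(name_or_config) && length(name_or_config) == 1) {
    if (name_or_config %in% builtin_architectures()) {
      path <- system.file("extdata", "circuits",
                          paste0(name_or_config, ".yaml"),
                          package = "optobalance", mustWork = TRUE)
      cfg <- yaml::read_yaml(path)
    } else if (file.exists(name_or_config)) {
      cfg <- yaml::read_yaml(name_or_config)
    } else {
      abort(paste0(
        "unknown architecture '", name_or_config, "'; available: ",
        paste(builtin_architectures(), collapse = ", "),
        " (or a YAML path / config list)"
      ))
    }
  } else {
    abort("supply an architecture name, a YAML path, or a config list")
  }
  if (!is.null(cfg$j)) {  # finite-size parameterization
    if (is.null(cfg$sizes$K)) abort("finite-size couplings 'j' require sizes$K")
    K <- cfg$sizes$K
    cfg$J <- lapply(cfg$j, function(row) lapply(row, function(x) x * sqrt(K)))
    cfg$j <- NULL
    if (!is.null(cfg$j0)) {
      cfg$J0 <- lapply(cfg$j0, function(x) x * sqrt(K))
      cfg$j0 <- NULL
    }
  }
  circuit_spec(
    populations = cfg$populations, polarity = cfg$polarity,
    J = cfg$J, J0 = cfg$J0, tau = cfg$tau, neuron = cfg$neuron,
    r0 = cfg$r0 %||% 5, sizes = cfg$sizes, opto = cfg$opto,
    name = cfg$name %||% "custom"
  )
}

#' @rdname load_architecture
#' @export
builtin_architectures <- function() {
  c("two_pop", "two_pop_noEE", "model1_nonparadox", "model1_paradox", "model2")
}

#' Serialize a circuit specification to YAML
#'
#' Writes the same schema [load_architecture()] reads, so that a
#' write-then-load round trip reproduces the spec exactly.
#'
#' @param spec a [circuit_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(spec, path) {
  pops <- spec$populations
  mat_to_list <- function(M, drop_na = FALSE) {
    out <- lapply(pops, function(post) {
      row <- M[post, ]
      keep <- if (drop_na) !is.na(row) else rep(TRUE, length(row))
      as.list(row[keep])
    })
    setNames(out, pops)
  }
  cfg <- list(
    name = spec$name,
    populations = pops,
    polarity = as.list(spec$polarity),
    J0 = as.list(spec$J0),
    J = mat_to_list(spec$J),
    tau = mat_to_list(spec$tau, drop_na = TRUE),
    neuron = list(C_M = spec$neuron$C_M, V_th = spec$neuron$V_th,
                  V_R = spec$neuron$V_R, g_leak = as.list(spec$neuron$g_leak)),
    r0 = spec$r0,
    sizes = if (!is.null(spec$sizes)) {
      list(counts = as.list(spec$sizes$N), K = spec$sizes$K)
    },
    opto = list(targets = as.list(spec$opto$targets), I0 = spec$opto$I0,
                Gamma0 = spec$opto$Gamma0)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Scale dimensionless couplings to a finite in-degree K
#'
#' In the strong-coupling framework, individual synapses scale as
#' `j = J / sqrt(K)` so that the summed input from each presynaptic population
#' is of order `sqrt(K)` times the rheobase. The feedforward drive is the
#' deterministic constant current `Lambda_ext = 2 * K * j0 * r0` (uA/cm^2,
#' with `r0` converted to ms^-1), equivalent to `2K` external Poisson inputs
#' at rate `r0` in the mean. The optogenetic current is boosted as
#' `Lambda_opto = sqrt(K) * I_opto` to keep its effect on rates K-independent.
#'
#' @param spec a [circuit_spec()].
#' @param K mean in-degree per presynaptic population (>= 1).
#' @return A list with `j` (uA.ms/cm^2 matrix), `j_signed`
#'   (`j * polarity[pre]`), `lambda_ext` (named, uA/cm^2), and
#'   `lambda_opto(Gamma)` returning the per-population optogenetic current
#'   (uA/cm^2) at laser intensity `Gamma`.
#' @examples
#' sc <- scale_to_finite_K(load_architecture("two_pop"), K = 500)
#' sc$j["E", "I"]        # 30 / sqrt(500)
#' sc$lambda_ext[["E"]]  # 2 * 500 * (17/sqrt(500)) * 0.005
#' @export
scale_to_finite_K <- function(spec, K = spec$sizes$K) {
  stopifnot(K >= 1)
  pops <- spec$populations
  j <- spec$J / sqrt(K)
  j_signed <- sweep(j, 2, spec$polarity, `*`)
  r0_ms <- spec$r0 / 1000  # Hz -> ms^-1
  lambda_ext <- 2 * K * (spec$J0 / sqrt(K)) * r0_ms  # uA/cm^2
  opto <- spec$opto
  lambda_opto <- function(Gamma) {
    I_nA <- opto_current(Gamma, opto)                # nA/cm^2
    out <- setNames(rep(0, length(pops)), pops)
    out[intersect(opto$targets, pops)] <- sqrt(K) * I_nA / 1000  # uA/cm^2
    out
  }
  list(K = K, j = j, j_signed = j_signed, lambda_ext = lambda_ext,
       lambda_opto = lambda_opto)
}

#' Signed effective interaction matrix
#'
#' Returns `A` with `A[post, pre] = polarity[pre] * J[post, pre]`. The
#' balance equations read `2 * J0 * r0 + I_opto + A %*% r = 0`, so `A`
#' determines both the balanced rates and the susceptibility structure.
#'
#' @param spec a [circuit_spec()].
#' @return A signed matrix with population dimnames.
#' @export
effective_matrix <- function(spec) {
  sweep(spec$J, 2, spec$polarity, `*`)
}

#' Diagnose a circuit specification
#'
#' Returns a tibble of diagnostics rather than raising conditions: negative
#' interaction strengths and inconsistent `J`/`tau` patterns are errors;
#' deviations from the canonical structural zeros of a recognized topology
#' (for instance a PV-to-SOM connection in the V1-like circuit, which is
#' reported in some areas and does not qualitatively change the PC and PV
#' responses) are warnings.
#'
#' @param spec a [circuit_spec()] (or a list with the same fields).
#' @return A tibble with columns `field`, `severity` (`"error"`/`"warning"`),
#'   and `message`; zero rows when the spec is clean.
#' @export
validate_spec <- function(spec) {
  out <- list()
  add <- function(field, severity, message) {
    out[[length(out) + 1]] <<- tibble(field = field, severity = severity,
                                      message = message)
  }
  pops <- spec$populations
  J <- spec$J; tau <- spec$tau
  if (any(J < 0)) {
    bad <- which(J < 0, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      add(paste0("J[", pops[bad[k, 1]], ",", pops[bad[k, 2]], "]"),
          "error", "negative strength")
    }
  }
  if (any(spec$J0 < 0, na.rm = TRUE)) add("J0", "error", "negative strength")
  if (!all(spec$polarity %in% c(-1, 1))) {
    add("polarity", "error", "polarities must be +1 or -1")
  }
  miss_tau <- J > 0 & is.na(tau)
  if (any(miss_tau)) {
    bad <- which(miss_tau, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      add(paste0("tau[", pops[bad[k, 1]], ",", pops[bad[k, 2]], "]"),
          "error", "synaptic time constant missing for a nonzero interaction")
    }
  }
  stray_tau <- J == 0 & !is.na(tau)
  if (any(stray_tau)) {
    bad <- which(stray_tau, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      add(paste0("tau[", pops[bad[k, 1]], ",", pops[bad[k, 2]], "]"),
          "warning", "time constant given for a zero-strength interaction")
    }
  }
  if (any(!is.na(tau) & tau <= 0)) add("tau", "error", "nonpositive time constant")
  nn <- spec$neuron
  if (!is.null(nn)) {
    if (!is.null(nn$V_th) && !is.null(nn$V_R) && nn$V_th <= nn$V_R) {
      add("neuron", "error", "V_th must exceed V_R")
    }
    if (!is.null(nn$C_M) && nn$C_M <= 0) add("neuron", "error", "C_M must be positive")
    if (any(nn$g_leak <= 0, na.rm = TRUE)) add("neuron", "error", "g_leak must be positive")
  }
  if (!is.null(spec$sizes) && !is.null(spec$sizes$K)) {
    if (any(spec$sizes$K > spec$sizes$N, na.rm = TRUE)) {
      add("sizes", "error", "in-degree K exceeds a population size")
    }
  }
  # structural zeros of the recognized four-population topologies
  topo <- circuit_topology(spec)
  zero_cells <- switch(
    topo,
    model1 = list(c("E", "V"), c("I", "V"), c("S", "I"), c("S", "S"), c("V", "V")),
    model2 = list(c("S", "S"), c("S", "X"), c("X", "I")),
    NULL
  )
  for (cell in zero_cells) {
    if (J[cell[1], cell[2]] != 0) {
      add(paste0("J[", cell[1], ",", cell[2], "]"), "warning",
          "nonzero where the canonical architecture has a structural zero")
    }
  }
  if (topo %in% c("model1", "model2") && spec$J0[["S"]] != 0) {
    add("J0[S]", "warning",
        "SOM receives no feedforward input in the canonical architecture")
  }
  if (length(out) == 0) {
    return(tibble(field = character(), severity = character(),
                  message = character()))
  }
  bind_rows(out)
}

#' Recognize the circuit topology from its population set
#' @param spec a [circuit_spec()].
#' @return One of `"two_pop"`, `"three_pop"`, `"model1"`, `"model2"`, or
#'   `"generic"`.
#' @keywords internal
circuit_topology <- function(spec) {
  pops <- spec$populations
  if (setequal(pops, c("E", "I"))) return("two_pop")
  if (setequal(pops, c("E", "I", "S"))) return("three_pop")
  if (setequal(pops, c("E", "I", "S", "V"))) return("model1")
  if (setequal(pops, c("E", "I", "S", "X"))) return("model2")
  "generic"
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec '", x$name, "'>\n", sep = "")
  cat("  populations:",
      paste0(x$populations, " (", ifelse(x$polarity > 0, "+", "-"), ")",
             collapse = ", "), "\n")
  cat("  J (uA.ms/cm^2), rows post / cols pre:\n")
  print(x$J)
  cat("  J0:", paste0(x$populations, "=", x$J0, collapse = ", "),
      " r0 =", x$r0, "Hz\n")
  if (!is.null(x$sizes)) {
    cat("  sizes: N =", sum(x$sizes$N), " K =", x$sizes$K, "\n")
  }
  cat("  opto: targets ", paste(x$opto$targets, collapse = ","),
      ", I0 = ", x$opto$I0, " nA/cm^2, Gamma0 = ", x$opto$Gamma0,
      " mW/mm^2\n", sep = "")
  invisible(x)
}
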