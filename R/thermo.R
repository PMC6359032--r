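## Antioxidant mechanism thermodynamics: the HAT / SET-PT / SPLET cycle
## quantities BDE, IP, PDE, PA, ETE per abstractable O-H site, their
## closure identities, and mechanism / site ranking.

# gas-phase closure constant H(H+) + H(e-) - H(H.) for a medium (kcal/mol)
.cycle_constant <- function(m) m$H_proton + m$H_electron - m$H_hydrogen

#' Full mechanism profile from species enthalpies
#'
#' From the enthalpies of the parent molecule ROH, its radical cation
#' ROH.+, radical RO. and anion RO- (kcal/mol) and the medium's reference
#' enthalpies, computes
#' \deqn{BDE = H(RO.) + H(H.) - H(ROH)}
#' \deqn{IP  = H(ROH.+) + H(e-) - H(ROH)}
#' \deqn{PDE = H(RO.) + H(H+) - H(ROH.+)}
#' \deqn{PA  = H(RO-) + H(H+) - H(ROH)}
#' \deqn{ETE = H(RO.) + H(e-) - H(RO-)}
#' These satisfy the closure identity
#' \eqn{IP + PDE = PA + ETE = BDE + [H(H+) + H(e-) - H(H.)]} exactly; the
#' residuals are reported as a numerical check.
#'
#' @param h_parent,h_cation,h_radical,h_anion species enthalpies in
#'   kcal/mol (vectors allowed, one entry per site).
#' @param medium a [medium()] or a name resolvable via `media`; must carry
#'   all three reference enthalpies.
#' @param site optional site label(s) (e.g. `"O7-H"`).
#' @param media media table for name resolution.
#' @return data.frame with columns `site`, `bde`, `ip`, `pde`, `pa`,
#'   `ete`, the closure residuals `closure_setpt` (IP+PDE side) and
#'   `closure_splet` (PA+ETE side) relative to BDE + cycle constant, and
#'   `preferred` (first-step minimum of \{BDE, IP, PA\}; ties joined with
#'   `"+"`).
#' @export
mechanism_profile <- function(h_parent, h_cation, h_radical, h_anion,
                              medium = "gas", site = NULL,
                              media = default_media()) {
  for (nm in c("h_parent", "h_cation", "h_radical", "h_anion")) {
    v <- get(nm)
    if (is.null(v) || anyNA(v))
      stop("contract error: missing species enthalpy ", nm)
  }
  m <- resolve_medium(medium, media, require_refs = TRUE)
  bde <- h_radical + m$H_hydrogen - h_parent
  ip  <- h_cation + m$H_electron - h_parent
  pde <- h_radical + m$H_proton - h_cation
  pa  <- h_anion + m$H_proton - h_parent
  ete <- h_radical + m$H_electron - h_anion
  k <- .cycle_constant(m)
  out <- data.frame(
    site = if (is.null(site)) paste0("site", seq_along(bde)) else site,
    medium = m$name,
    bde = bde, ip = ip, pde = pde, pa = pa, ete = ete,
    closure_setpt = ip + pde - (bde + k),
    closure_splet = pa + ete - (bde + k))
  out$preferred <- preferred_mechanism(bde, ip, pa)
  out
}

#' Complete a partially known thermodynamic cycle
#'
#' Given any solvable subset of \{BDE, IP, PDE, PA, ETE\}, infers the
#' remaining quantities from the cycle identities
#' \eqn{IP + PDE = PA + ETE} and, when the medium's reference enthalpies
#' are available, \eqn{IP + PDE = BDE + [H(H+) + H(e-) - H(H.)]}.
#'
#' @param known named list or named numeric vector with a subset of
#'   `bde`, `ip`, `pde`, `pa`, `ete` (kcal/mol).
#' @param medium a [medium()] or name; reference enthalpies are used only
#'   if present (identities that need none still work without them).
#' @param media media table for name resolution.
#' @return named numeric vector of all five quantities (`NA` where a
#'   quantity cannot be determined from the given subset), with attribute
#'   `inferred` naming the quantities that were filled in; a subset from
#'   which nothing new can be derived is an inference error.
#' @examples
#' complete_cycle(c(bde = 108.41, ip = 200.81), "gas")  # PDE = 222.13
#' @export
complete_cycle <- function(known, medium = "gas", media = default_media()) {
  q <- c(bde = NA_real_, ip = NA_real_, pde = NA_real_, pa = NA_real_,
         ete = NA_real_)
  known <- unlist(known)
  names(known) <- tolower(names(known))
  bad <- setdiff(names(known), names(q))
  if (length(bad)) stop("unknown cycle quantity: ", paste(bad, collapse = ", "))
  q[names(known)] <- known
  m <- resolve_medium(medium, media)
  k <- if (all(is.finite(c(m$H_hydrogen, m$H_electron, m$H_proton))))
    .cycle_constant(m) else NA_real_
  given <- names(q)[is.finite(q)]
  # fixed-point pass over the two identities and their rearrangements
  repeat {
    before <- sum(is.finite(q))
    # IP + PDE = PA + ETE
    if (!is.finite(q["ete"]) && all(is.finite(q[c("ip", "pde", "pa")])))
      q["ete"] <- q[["ip"]] + q[["pde"]] - q[["pa"]]
    if (!is.finite(q["pa"]) && all(is.finite(q[c("ip", "pde", "ete")])))
      q["pa"] <- q[["ip"]] + q[["pde"]] - q[["ete"]]
    if (!is.finite(q["pde"]) && all(is.finite(q[c("pa", "ete", "ip")])))
      q["pde"] <- q[["pa"]] + q[["ete"]] - q[["ip"]]
    if (!is.finite(q["ip"]) && all(is.finite(q[c("pa", "ete", "pde")])))
      q["ip"] <- q[["pa"]] + q[["ete"]] - q[["pde"]]
    # BDE + k = IP + PDE (and = PA + ETE)
    if (is.finite(k)) {
      if (!is.finite(q["pde"]) && all(is.finite(q[c("bde", "ip")])))
        q["pde"] <- q[["bde"]] + k - q[["ip"]]
      if (!is.finite(q["ip"]) && all(is.finite(q[c("bde", "pde")])))
        q["ip"] <- q[["bde"]] + k - q[["pde"]]
      if (!is.finite(q["ete"]) && all(is.finite(q[c("bde", "pa")])))
        q["ete"] <- q[["bde"]] + k - q[["pa"]]
      if (!is.finite(q["pa"]) && all(is.finite(q[c("bde", "ete")])))
        q["pa"] <- q[["bde"]] + k - q[["ete"]]
      if (!is.finite(q["bde"]) && all(is.finite(q[c("ip", "pde")])))
        q["bde"] <- q[["ip"]] + q[["pde"]] - k
      if (!is.finite(q["bde"]) && all(is.finite(q[c("pa", "ete")])))
        q["bde"] <- q[["pa"]] + q[["ete"]] - k
    }
    if (sum(is.finite(q)) == before) break
  }
  inferred <- setdiff(names(q)[is.finite(q)], given)
  if (length(inferred) == 0L)
    stop("inference error: cycle under-determined from {",
         paste(given, collapse = ", "), "}",
         if (!is.finite(k)) " (no reference enthalpies for this medium)")
  attr(q, "inferred") <- inferred
  q
}

#' Thermodynamically preferred radical-scavenging mechanism
#'
#' Compares the first-step enthalpies of the three pathways - HAT (BDE),
#' SET-PT (IP) and SPLET (PA) - and returns the mechanism with the lowest
#' first step. Exact ties return all tied labels joined with `"+"`.
#'
#' @param bde,ip,pa first-step enthalpies in kcal/mol (vectors allowed).
#' @return character vector of mechanism labels (`"HAT"`, `"SET-PT"`,
#'   `"SPLET"`, or tie combinations).
#' @export
preferred_mechanism <- function(bde, ip, pa) {
  if (anyNA(c(bde, ip, pa)))
    stop("contract error: BDE, IP and PA all required")
  mapply(function(b, i, p) {
    v <- c(HAT = b, `SET-PT` = i, SPLET = p)
    paste(names(v)[v == min(v)], collapse = "+")
  }, bde, ip, pa, USE.NAMES = FALSE)
}

#' Rank O-H sites by a cycle quantity
#'
#' @param profiles data.frame with a `site` column and cycle-quantity
#'   columns (e.g. from [mechanism_profile()] or a printed table).
#' @param quantity which column to sort by (`"bde"`, `"pa"`, ...).
#' @return the rows sorted ascending by the quantity (minimum - the most
#'   reactive site - first); ties broken by site label.
#' @export
rank_sites <- function(profiles, quantity = "bde") {
  quantity <- tolower(quantity)
  if (!quantity %in% tolower(names(profiles)))
    stop("quantity '", quantity, "' not found in profiles")
  names(profiles) <- tolower(names(profiles))
  if (nrow(profiles) < 1L) stop("at least one site required")
  out <- profiles[order(profiles[[quantity]], profiles$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}
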