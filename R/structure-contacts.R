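# Typed contact detection on heavy-atom coordinates: hydrogen bonds, salt
# bridges and non-polar packing, each tagged intra- or inter-protomer.

.pair_distances <- function(a, b) {
  ca <- as.matrix(a[, c("x", "y", "z")])
  cb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rep(1, nrow(cb))) +
    outer(rep(1, nrow(ca)), rowSums(cb^2)) - 2 * ca %*% t(cb)
  sqrt(pmax(d2, 0))
}

.angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
}

#' Detect typed residue contacts
#'
#' Heavy-atom contact criteria (no hydrogens required):
#' * hydrogen bond: donor-acceptor distance <= `hbond_dist` (3.5 A) and an
#'   antecedent-donor-acceptor angle >= `hbond_angle_min` (90 deg);
#' * salt bridge: side-chain N+/O- group atoms of oppositely charged
#'   residues (Asp/Glu vs Lys/Arg/His) within `salt_dist` (4.0 A);
#' * nonpolar: side-chain carbon-carbon pairs of apolar residues within
#'   `nonpolar_dist` (4.5 A).
#'
#' One contact is reported per residue pair and kind, at the closest
#' qualifying atom pair, and tagged `intra` or `inter` by chain.
#'
#' @param struct Atom tibble.
#' @param model Model number.
#' @param hbond_dist,salt_dist,nonpolar_dist Distance cutoffs, Angstrom.
#' @param hbond_angle_min Minimum antecedent-donor-acceptor angle, degrees.
#' @return Tibble with columns `kind`, `chain_a`, `resno_a`, `resname_a`,
#'   `atom_a`, `chain_b`, `resno_b`, `resname_b`, `atom_b`, `distance`,
#'   `angle` (hydrogen bonds only) and `span` (`intra`/`inter`).
#' @export
find_contacts <- function(struct, model = 1, hbond_dist = 3.5,
                          salt_dist = 4.0, nonpolar_dist = 4.5,
                          hbond_angle_min = 90) {
  struct <- .validate_struct(struct)
  d <- struct[struct$model == model & struct$element != "H", ]
  d$idx <- seq_len(nrow(d))
  res_key <- function(t) paste(t$chain, t$resno, sep = ":")

  contacts <- list()
  add <- function(kind, a, b, distance, angle = NA_real_) {
    contacts[[length(contacts) + 1L]] <<- tibble::tibble(
      kind = kind,
      chain_a = a$chain, resno_a = a$resno, resname_a = a$resname,
      atom_a = a$atom,
      chain_b = b$chain, resno_b = b$resno, resname_b = b$resname,
      atom_b = b$atom,
      distance = distance, angle = angle,
      span = if (a$chain == b$chain) "intra" else "inter"
    )
  }

  # ---- hydrogen bonds -----------------------------------------------------
  don <- dplyr::bind_rows(
    d[d$atom == "N" & d$resname != "PRO", ],
    dplyr::inner_join(d, .hb_donors[.hb_donors$resname != "*", ],
                      by = c("resname", "atom"))
  )
  don$antecedent <- ifelse(don$atom == "N", "CA",
                           don$antecedent %||% NA_character_)
  acc <- dplyr::bind_rows(
    d[d$atom %in% c("O", "OXT"), ],
    dplyr::inner_join(d, .hb_acceptors[.hb_acceptors$resname != "*", ],
                      by = c("resname", "atom"))
  )
  if (nrow(don) && nrow(acc)) {
    dm <- .pair_distances(don, acc)
    hits <- which(dm <= hbond_dist, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]; j <- hits[h, 2]
      a <- don[i, ]; b <- acc[j, ]
      if (a$chain == b$chain && abs(a$resno - b$resno) < 2) next
      ant <- d[d$chain == a$chain & d$resno == a$resno &
                 d$atom == a$antecedent, ]
      if (nrow(ant) != 1) next
      ang <- .angle_deg(c(ant$x, ant$y, ant$z), c(a$x, a$y, a$z),
                        c(b$x, b$y, b$z))
      if (ang >= hbond_angle_min) add("hbond", a, b, dm[i, j], ang)
    }
  }

  # ---- salt bridges -------------------------------------------------------
  neg <- dplyr::inner_join(d, .sb_negative, by = c("resname", "atom"))
  pos <- dplyr::inner_join(d, .sb_positive, by = c("resname", "atom"))
  if (nrow(neg) && nrow(pos)) {
    dm <- .pair_distances(neg, pos)
    hits <- which(dm <= salt_dist, arr.ind = TRUE)
    if (nrow(hits)) {
      ht <- tibble::tibble(i = hits[, 1], j = hits[, 2],
                           dist = dm[hits],
                           pair = paste(res_key(neg[hits[, 1], ]),
                                        res_key(pos[hits[, 2], ])))
      ht <- ht |> dplyr::group_by(.data$pair) |>
        dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      for (h in seq_len(nrow(ht))) {
        add("salt_bridge", neg[ht$i[h], ], pos[ht$j[h], ], ht$dist[h])
      }
    }
  }

  # ---- nonpolar packing ---------------------------------------------------
  ap <- d[d$resname %in% .apolar_residues & d$element == "C" &
            !(d$atom %in% c("N", "CA", "C", "O")), ]
  if (nrow(ap) > 1) {
    dm <- .pair_distances(ap, ap)
    hits <- which(dm <= nonpolar_dist & upper.tri(dm), arr.ind = TRUE)
    if (nrow(hits)) {
      keep <- vapply(seq_len(nrow(hits)), function(h) {
        a <- ap[hits[h, 1], ]; b <- ap[hits[h, 2], ]
        !(a$chain == b$chain && abs(a$resno - b$resno) < 2)
      }, logical(1))
      hits <- hits[keep, , drop = FALSE]
      if (nrow(hits)) {
        ht <- tibble::tibble(i = hits[, 1], j = hits[, 2], dist = dm[hits],
                             pair = paste(res_key(ap[hits[, 1], ]),
                                          res_key(ap[hits[, 2], ])))
        ht <- ht |> dplyr::group_by(.data$pair) |>
          dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
          dplyr::ungroup()
        for (h in seq_len(nrow(ht))) {
          add("nonpolar", ap[ht$i[h], ], ap[ht$j[h], ], ht$dist[h])
        }
      }
    }
  }

  if (!length(contacts)) {
    return(tibble::tibble(
      kind = character(), chain_a = character(), resno_a = integer(),
      resname_a = character(), atom_a = character(), chain_b = character(),
      resno_b = integer(), resname_b = character(), atom_b = character(),
      distance = numeric(), angle = numeric(), span = character()))
  }
  dplyr::arrange(dplyr::bind_rows(contacts), .data$kind, .data$chain_a,
                 .data$resno_a)
}
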