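# shared fixture builders: every table is generated in code

two_atom_dist <- function(c1 = 6, c2 = 60) {
  to_distribution(atom_table(c(c1, c2), c(0.5, 0.5)))
}

# random valid Siler tables, one per index, deterministic
random_tables <- function(n, seed = 42) {
  lapply(random_siler_params(n, seed = seed), make_lifetable)
}

# rescale all ages by lambda (x, widths, a); boundary at 15 is preserved
# for lambda in {3, 1/3} since the standard layout has boundaries at 5 and 45
scale_table <- function(lt, lambda) {
  iv <- lt$intervals
  abridged_lifetable(x = iv$x * lambda, n = iv$n * lambda, d = iv$d,
                     a = iv$a * lambda, radix = lt$radix, meta = lt$meta)
}

# shift all ages by delta >= 0 (prepend a zero-death interval [0, delta))
shift_table <- function(lt, delta) {
  iv <- lt$intervals
  abridged_lifetable(x = c(0, iv$x + delta), n = c(delta, iv$n),
                     d = c(0, iv$d), a = c(delta / 2, iv$a),
                     radix = lt$radix, meta = lt$meta)
}

# write a WPP-dialect CSV for a list of tables
write_wpp_fixture <- function(tables, path) {
  rows <- lapply(tables, function(lt) {
    iv <- lt$intervals
    span <- ifelse(is.na(iv$n), -1, iv$n)
    data.frame(Location = lt$meta$country %||% "X",
               Time = lt$meta$year %||% 2000,
               Sex = lt$meta$sex %||% "both",
               AgeGrpStart = iv$x, AgeGrpSpan = span,
               dx = iv$d, ax = iv$a,
               lx = if (!is.null(iv$l)) iv$l else NA,
               ex = if (!is.null(iv$e)) iv$e else NA)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$lx))) out$lx <- NULL
  if (all(is.na(out$ex))) out$ex <- NULL
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
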