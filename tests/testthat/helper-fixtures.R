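# Shared fixtures and test-side oracles. Everything here is generated in
# code; the two-state benchmark is memoised because several files use it.

.fixtureCache <- new.env(parent = emptyenv())

twoStateFixture <- function(noise = 0, seed = 1L, nUnits = 5L) {
  key <- sprintf("ts_%g_%d_%d", noise, seed, nUnits)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateTwoState(
      syntheticSpec(noise = noise, seed = seed, nUnits = nUnits))
  .fixtureCache[[key]]
}

# Independent brute-force minimum CA-CA distance: nested loops over every
# site pair, written from the definition, never touching package internals.
oracleMinDist <- function(model, map, p1, r1, p2, r2) {
  a <- atoms(model)
  m <- chainMapTable(map)
  ch1 <- m$chain[tolower(trimws(m$protein)) == tolower(trimws(p1))]
  ch2 <- m$chain[tolower(trimws(m$protein)) == tolower(trimws(p2))]
  s1 <- a[a$chain %in% ch1 & a$resno == r1 & a$elety == "CA", ]
  s2 <- a[a$chain %in% ch2 & a$resno == r2 & a$elety == "CA", ]
  if (nrow(s1) == 0 || nrow(s2) == 0) return(NA_real_)
  same <- tolower(trimws(p1)) == tolower(trimws(p2)) && r1 == r2
  best <- Inf
  for (i in seq_len(nrow(s1))) {
    for (j in seq_len(nrow(s2))) {
      if (same && s1$chain[i] == s2$chain[j]) next
      d <- sqrt(sum((c(s1$x[i], s1$y[i], s1$z[i]) -
                       c(s2$x[j], s2$y[j], s2$z[j]))^2))
      best <- min(best, d)
    }
  }
  if (is.finite(best)) best else NA_real_
}

# Random multi-copy bead assembly for oracle-equivalence properties:
# nProteins proteins with up to maxCopies copies each, nRes residues per
# chain, coordinates uniform in a box.
randomAssembly <- function(nProteins = 3L, maxCopies = 5L, nRes = 6L,
                           box = 60) {
  rows <- list(); mapRows <- list()
  ci <- 0L
  for (p in seq_len(nProteins)) {
    copies <- sample.int(maxCopies, 1)
    for (cp in seq_len(copies)) {
      ci <- ci + 1L
      ch <- sprintf("c%02d", ci)
      rows[[ci]] <- data.frame(
        chain = ch, resno = seq_len(nRes), resid = "ALA", elety = "CA",
        element = "C", x = runif(nRes, 0, box), y = runif(nRes, 0, box),
        z = runif(nRes, 0, box), b = 90, stringsAsFactors = FALSE)
      mapRows[[ci]] <- data.frame(
        chain = ch, protein = sprintf("PROT%d", p), copy = cp,
        subcomplex = "other", unit = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  list(model = assemblyModel(do.call(rbind, rows)),
       map = chainMap(do.call(rbind, mapRows)))
}

# Minimal hand-built model: two proteins, two copies each, known geometry.
tinyModel <- function() {
  at <- rbind(
    data.frame(chain = "A", resno = 1:3, resid = "ALA", elety = "CA",
               element = "C", x = c(0, 4, 8), y = 0, z = 0, b = c(90, 30, 90)),
    data.frame(chain = "B", resno = 1:3, resid = "ALA", elety = "CA",
               element = "C", x = c(0, 4, 8), y = 20, z = 0, b = 90),
    data.frame(chain = "C", resno = 1:2, resid = "GLY", elety = "CA",
               element = "C", x = c(50, 54), y = 0, z = 0, b = c(40, 90)))
  map <- chainMap(data.frame(
    chain = c("A", "B", "C"), protein = c("PROTX", "PROTX", "PROTY"),
    copy = c(1L, 2L, 1L), subcomplex = "other", unit = NA_integer_,
    stringsAsFactors = FALSE))
  list(model = assemblyModel(at), map = map)
}

# Plain connected-components on the inter-residue distance graph, used as
# the clustering oracle.
oracleComponents <- function(residues, model, cutoff) {
  a <- atoms(model)
  n <- nrow(residues)
  coords <- lapply(seq_len(n), function(i)
    as.matrix(a[a$chain == residues$chain[i] & a$resno == residues$resno[i],
                c("x", "y", "z"), drop = FALSE]))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dmin <- Inf
    for (u in seq_len(nrow(coords[[i]]))) for (v in seq_len(nrow(coords[[j]])))
      dmin <- min(dmin, sqrt(sum((coords[[i]][u, ] - coords[[j]][v, ])^2)))
    adj[i, j] <- dmin < cutoff
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}
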