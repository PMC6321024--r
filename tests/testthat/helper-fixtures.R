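# Shared helpers for the test suite. Everything is generated in code;
# nothing is downloaded.

# Reduced engine settings for pipeline-level tests where pose precision is
# not under test (full defaults are exercised in the pose-recovery tests).
light_dock_params <- function() {
  dock_params(n_rot = 12L, k_keep = 8L, n_refine = 4L, max_iter = 40L)
}

# A loaded toy entry plus its extracted ligand, site and potential.
toy_setup <- function(seed = 1L, params = site_db_params(), ...) {
  entry <- load_structure(make_toy_complex(seed = seed, ...),
                          entry_id = sprintf("toy%02d", seed))
  lig <- extract_candidate_ligands(entry, "A", params)[[1]]
  site <- make_centroids(make_binding_site(entry, "A", lig, params))
  protein <- protein_for_docking(entry, "A")
  pot <- derive_pair_potential(list(complex_from_entry(entry, "A", lig)))
  list(entry = entry, lig = lig, site = site, protein = protein, pot = pot)
}

# Independent RDKit oracle (via the system python) for molecule counts;
# returns NULL if python/rdkit is unavailable so callers can fall back.
rdkit_counts <- function(smiles) {
  script <- sprintf(paste0(
    "from rdkit import Chem\n",
    "from rdkit.Chem import rdMolDescriptors\n",
    "m = Chem.MolFromSmiles(%s)\n",
    "print(m.GetNumHeavyAtoms(), m.GetNumBonds(),",
    " rdMolDescriptors.CalcNumAromaticRings(m))\n"), shQuote(smiles))
  out <- tryCatch(
    suppressWarnings(system2("python", "-", input = script,
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL
  )
  if (is.null(out) || !length(out)) return(NULL)
  v <- suppressWarnings(as.integer(strsplit(tail(out, 1), " ")[[1]]))
  if (length(v) != 3 || anyNA(v)) return(NULL)
  list(heavy = v[1], bonds = v[2], aromatic_rings = v[3])
}

# SMARTS-style rotatable-bond oracle via RDKit, applying the same rule
# (single, acyclic, both ends with >= 2 heavy neighbors, not amide).
rdkit_rotatable <- function(smiles) {
  script <- sprintf(paste0(
    "from rdkit import Chem\n",
    "m = Chem.MolFromSmiles(%s)\n",
    "patt = Chem.MolFromSmarts('[!D1;!$([*]#[*])]-&!@[!D1;!$([*]#[*])]')\n",
    "amide = Chem.MolFromSmarts('[C;$(C=O)]-&!@[N]')\n",
    "rot = set(frozenset(p) for p in m.GetSubstructMatches(patt))\n",
    "am = set(frozenset(p) for p in m.GetSubstructMatches(amide))\n",
    "print(len(rot - am))\n"), shQuote(smiles))
  out <- tryCatch(
    suppressWarnings(system2("python", "-", input = script,
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL
  )
  if (is.null(out) || !length(out)) return(NULL)
  as.integer(tail(out, 1))
}

CURCUMIN_SMILES <- "COc1cc(/C=C/C(=O)/C=C(O)/C=C/c2ccc(O)c(OC)c2)ccc1O"
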