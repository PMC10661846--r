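"""Seeded 3D embedding: distance-geometry conformer + UFF relaxation.

Reads a tab-separated "SMILES<TAB>title" file, writes an SDF. Molecules
that fail to parse or embed are omitted; the caller detects them by the
missing title.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

smi_path, out_path, seed = sys.argv[1], sys.argv[2], int(sys.argv[3])
writer = Chem.SDWriter(out_path)
for line in open(smi_path):
    line = line.rstrip("\n")
    if not line:
        continue
    smi, title = line.split("\t")
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        continue
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) != 0:
        if AllChem.EmbedMolecule(mol, useRandomCoords=True,
                                 randomSeed=seed) != 0:
            continue
    try:
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    except Exception:
        pass
    mol.SetProp("_Name", title)
    writer.write(mol)
writer.close()
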