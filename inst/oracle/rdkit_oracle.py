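"""Independent descriptor oracle: reads SMILES (one per line, tab-separated
id<TAB>smiles) on stdin, writes TSV id, formula, mw, rb, hbd, tpsa, wlogp,
canonical smiles.  Used by the test suite only."""
import sys
from rdkit import Chem
from rdkit.Chem import Descriptors, Crippen, rdMolDescriptors

# donor = N or O bearing at least one H (thiol S-H excluded, matching the
# convention of the printed descriptor tables)
HBD_PATTERN = Chem.MolFromSmarts('[#7,#8;!H0]')

print("id\tformula\tmw\trb\thbd\ttpsa\twlogp\tcanonical")
for line in sys.stdin:
    line = line.strip()
    if not line:
        continue
    ident, smi = line.split("\t")
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        print(f"{ident}\tPARSE_ERROR\tnan\t-1\t-1\tnan\tnan\t")
        continue
    rb = rdMolDescriptors.CalcNumRotatableBonds(
        mol, rdMolDescriptors.NumRotatableBondsOptions.NonStrict)
    print("\t".join([
        ident,
        rdMolDescriptors.CalcMolFormula(mol),
        f"{Descriptors.MolWt(mol):.4f}",
        str(rb),
        str(len(mol.GetSubstructMatches(HBD_PATTERN))),
        f"{rdMolDescriptors.CalcTPSA(mol, includeSandP=True):.4f}",
        f"{Crippen.MolLogP(mol):.4f}",
        Chem.MolToSmiles(mol),
    ]))
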