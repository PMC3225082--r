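<?xml version="1.0" encoding="UTF-8"?>
<wendi query="querycmpd" smiles="CCC(CO)NC(=O)C1CN(C)C2CC3=CN(C)C4=CC=CC(=C34)C2=C1">
  <group name="ActiveBioassay">
    <record cid="cid5486180" similarity="0.929">
      <bioassay aid="aid410" description="p450-cyp1a2"/>
    </record>
  </group>
  <group name="Literature">
    <record cid="ctdcid9681" similarity="1.000" name="Methysergide">
      <article id="pubmedid8743744" title="Serotonin receptor binding in human blood platelets">Radioligand displacement showed high-affinity binding consistent with the HTR1B receptor subtype.</article>
    </record>
    <record cid="ctdcid11865408" similarity="0.774" name="Metergoline">
      <article id="pubmedid1330643" title="Ergoline derivatives as serotonergic receptor ligands">Metergoline analogues displaced agonist binding at sites expressing HTR1B in transfected cells.</article>
    </record>
  </group>
</wendi>
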