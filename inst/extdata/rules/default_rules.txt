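# Default compound-to-disease rule base.
# r1-r3 are the published rules, kept verbatim; r4-r8 reconstruct the
# remaining evidence channels (CTD direct, anchored bioassay-gene, anchored
# literature co-occurrence, target channel, article-disease channel).

[r1: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:isActiveIn ?Bioassay),
     (?Bioassay wo:isAssociatedWith ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]

[r2: (?CompoundID wo:isContainedIn ?Journal),
     (?Journal wo:hasGene ?Gene),
     (?Gene wo:isAssociatedWith ?Disease)
  -> (?CompoundID wo:mightHasDisease ?Disease)]

[r3: (?CompoundID wo:isActiveIn ?Bioassay),
     (?Bioassay wo:hasGene ?Gene),
     (?Gene wo:isAssociatedWith ?Disease)
  -> (?CompoundID wo:mightHasDisease ?Disease)]

[r4: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:hasDisease ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]

[r5: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:isActiveIn ?Bioassay),
     (?Bioassay wo:hasGene ?Gene),
     (?Gene wo:isAssociatedWith ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]

[r6: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?Gene wo:isrelatedTo ?CompoundID),
     (?Gene wo:isAssociatedWith ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]

[r7: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:hasGene ?Gene),
     (?Gene wo:isAssociatedWith ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]

[r8: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:isContainedIn ?Journal),
     (?Journal wo:hasDisease ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]
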