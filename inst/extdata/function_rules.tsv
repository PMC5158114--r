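# Ordered keyword rules mapping free-text annotations to functional groups.
# First matching pattern (case-insensitive regex) wins; no match -> "Unknown function".
pattern	group
lipase|phospholipase|esterase|acyl[- ]?CoA|fatty[- ]acid|lipid|ketothiolase|acetoacet|enoyl|hydroxyacyl|hydroxybutyr|phasin|polyhydroxyalkanoa|hydroxyalkanoic|acyl carrier|\[?ACP\]?|malonyl|ketogenes|acetyl[- ]?(co)?[- ]?enzyme[- ]?A|acetyl[- ]?CoA|propionyl[- ]?CoA|glycerol-3-phosphate	Lipid metabolism and ketogenesis
transport|secretion|efflux|porin|channel|permease|ABC[- ]transporter|TonB|siderophore|flagell|pilus|secretin	Transport, secretion, and efflux
chaperon|heat[- ]shock|cold[- ]shock|catalase|superoxide|peroxidase|peroxiredoxin|thioredoxin|stress|protease inhibitor|osmotic	Stress and defense mechanisms
ribosom|RNA polymerase|DNA polymerase|helicase|gyrase|topoisomerase|transcription|translation|elongation factor|DNA repair|recombinase|histone|nucleotid	Replication, transcription, translation, and DNA repair
glycos[iy]l|xylanase|cellulase|amylase|glucosidase|galactosidase|glycolysis|glucokinase|phosphofructokinase|fructose-1,6-bisphosphat|sugar|carbohydrate|glycan|pectin	Carbohydrate metabolism
peptidase|protease|aminopeptidase|aminotransferase|glutamine synthetase|amino[- ]acid	Protein and amino acid metabolism
dehydrogenase|oxidoreductase|cytochrome|ATP synthase|NADH|electron transfer	Energy production and conversion
hypothetical|uncharacteri[sz]ed|unknown|DUF	Unknown function
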