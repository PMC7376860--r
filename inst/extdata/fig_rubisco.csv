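subject,kind,predicate,object
assembly of RuBisCO,type,ChaperonedComplexAssembly,
RBCL,type,SimpleProtein,
RBCS,type,SimpleProtein,
RBCX,type,SimpleProtein,
RAF1,type,SimpleProtein,
RBCL8-RBCS8 complex,type,GeneProduct,
chaperonin activity,type,ChaperoneActivity,
assembly of RuBisCO,property,has_input,RBCL
assembly of RuBisCO,property,has_input,RBCS
assembly of RuBisCO,property,has_output,RBCL8-RBCS8 complex
assembly of RuBisCO,property,mediated_by,RBCX
assembly of RuBisCO,property,mediated_by,RAF1
assembly of RuBisCO,property,requires,chaperonin activity
carbamylation of RuBisCO,type,ProteinCarbamylation,
CO2,type,Non-geneProduct,
carbamylated RuBisCO,type,GeneProduct,
carbamylation of RuBisCO,property,has_input,RBCL8-RBCS8 complex
carbamylation of RuBisCO,property,has_input,CO2
carbamylation of RuBisCO,property,has_output,carbamylated RuBisCO
Mg2+ binding to RuBisCO,type,MetalIonBinding,
Mg2+,type,Non-geneProduct,
RuBisCO holoenzyme,type,GeneProduct,
Mg2+ binding to RuBisCO,property,has_input,carbamylated RuBisCO
Mg2+ binding to RuBisCO,property,has_input,Mg2+
Mg2+ binding to RuBisCO,property,has_output,RuBisCO holoenzyme
"carboxylation of D-ribulose 1,5-bisphosphate",type,MetabolicCarboxylation,
"D-ribulose 1,5-bisphosphate",type,Non-geneProduct,
3-Phosphoglycerate,type,Non-geneProduct,
ribulose-bisphosphate carboxylase activity,type,CarboxylaseActivity,
"carboxylation of D-ribulose 1,5-bisphosphate",property,has_input,"D-ribulose 1,5-bisphosphate"
"carboxylation of D-ribulose 1,5-bisphosphate",property,has_input,CO2
"carboxylation of D-ribulose 1,5-bisphosphate",property,has_output,3-Phosphoglycerate
"carboxylation of D-ribulose 1,5-bisphosphate",property,mediated_by,RuBisCO holoenzyme
"carboxylation of D-ribulose 1,5-bisphosphate",property,requires,ribulose-bisphosphate carboxylase activity
"oxygenation of D-ribulose 1,5-bisphosphate",type,MetabolicMonooxygenation,
O2,type,Non-geneProduct,
2-Phosphoglycolate,type,Non-geneProduct,
monooxygenase activity,type,MonooxygenaseActivity,
"oxygenation of D-ribulose 1,5-bisphosphate",property,has_input,"D-ribulose 1,5-bisphosphate"
"oxygenation of D-ribulose 1,5-bisphosphate",property,has_input,O2
"oxygenation of D-ribulose 1,5-bisphosphate",property,has_output,2-Phosphoglycolate
"oxygenation of D-ribulose 1,5-bisphosphate",property,has_output,3-Phosphoglycerate
"oxygenation of D-ribulose 1,5-bisphosphate",property,mediated_by,RuBisCO holoenzyme
"oxygenation of D-ribulose 1,5-bisphosphate",property,requires,monooxygenase activity
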