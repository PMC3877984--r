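# Medications and other drugs that may interfere with TSH and/or FT4
# measurements. One entry per line; matching is case-insensitive,
# whitespace-normalized, exact-name. Lines starting with '#' are ignored.
2-3-dimercatopropanol
2-4-dinitrophenol
5-fluorouracil
5-hydroxytryptophan
acetazolamide
acetylsalicylic acid
alpha adrenergic blockers
aminoglutethimide
aminotriazole
amiodarone
androgens and other anabolic steroids
anphenona
anphetamines
antipyrine
benserazide
beta adrenergic blockers
bexarotene
bromine
brompheniramine
cadmium
carbamazepine
chromate
chromium picolinate
cimetidine
clofibrate
clomiphene
clomipramine
cobalt
complex anions
corticosteroids
cytostatics
danazol
diphenylhydantoin
dinitrophenol
dobutamine
domperidone
dopamine and its agonists
other dopaminergic agents
erythrosine
estrogens
ethionamide
fenclofenac
fenoldopam
flunarizine
fluor
furosemide
fusaric acid
growth hormone (GH)
GH-releasing hormone
halofenate
heroin
heparin
interleukins
iopanoic acid
other radiological contrasts
other iodine-containing substances and drugs (potassium iodide and others)
insulin-like growth factor-1
interferon
ketoconazole
L-asparaginase
L-dopa inhibitors
levothyroxine
lithium
lovastatin
mefenamic acid
melatonin
metformin
methadone
methimazole
metoclopramide
mitotane
nevirapine
niacin
nicotinic acid
nifedipine
NSAIDs
nitrate
o,p'-DDD
orphenadrine
opioids
oxcarbazepine
para-aminobenzoic acid
perchlorate
perphenazine
phenidone
phenylbutazone
phenobarbital
pimozide
prazozin
primidone
propylthiouracil
pyridoxine
quetiapine
raloxifen
resorcinol
rifampicin
ritonavir
rubidium
salsalate
serotonergics antagonists
somatostatin and its analogues
spironolactone
St. John's Wort
stavudine
sulfonamides
sulfonylureas
sulpiride
steroids hormones
tamoxifen
thiocyanate
thyroid hormones and their analogs
troleandomycin
tyrosine kinase inhibitors
valproic acid
antidepressants
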