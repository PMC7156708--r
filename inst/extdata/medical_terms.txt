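aspirin
metformin
lisinopril
atorvastatin
simvastatin
insulin
warfarin
heparin
ibuprofen
acetaminophen
naproxen
prednisone
albuterol
omeprazole
pantoprazole
amlodipine
metoprolol
atenolol
carvedilol
losartan
hydrochlorothiazide
furosemide
spironolactone
gabapentin
pregabalin
sertraline
fluoxetine
citalopram
escitalopram
trazodone
amoxicillin
azithromycin
ciprofloxacin
doxycycline
cephalexin
vancomycin
ceftriaxone
levothyroxine
allopurinol
colchicine
methotrexate
hydroxychloroquine
sulfasalazine
etanercept
adalimumab
infliximab
rituximab
tacrolimus
cyclosporine
morphine
oxycodone
hydromorphone
fentanyl
tramadol
ondansetron
metoclopramide
diphenhydramine
loratadine
cetirizine
montelukast
tiotropium
ipratropium
budesonide
fluticasone
hypertension
hypotension
diabetes
mellitus
hyperlipidemia
hypothyroidism
hyperthyroidism
asthma
copd
emphysema
bronchitis
pneumonia
influenza
covid
infection
sepsis
bacteremia
cellulitis
abscess
anemia
thrombocytopenia
leukocytosis
neutropenia
lymphoma
leukemia
carcinoma
melanoma
sarcoma
metastasis
arthritis
osteoarthritis
rheumatoid
lupus
vasculitis
gout
fibromyalgia
osteoporosis
fracture
sprain
strain
migraine
seizure
epilepsy
stroke
ischemia
infarction
angina
arrhythmia
fibrillation
flutter
tachycardia
bradycardia
palpitations
murmur
stenosis
regurgitation
cardiomyopathy
pericarditis
endocarditis
embolism
thrombosis
aneurysm
atherosclerosis
gastritis
esophagitis
reflux
gerd
ulcer
pancreatitis
hepatitis
cirrhosis
cholecystitis
colitis
diverticulitis
appendicitis
obstruction
ileus
hernia
nephropathy
nephritis
pyelonephritis
cystitis
urinary
incontinence
retention
prostate
hyperplasia
dialysis
transplant
neuropathy
radiculopathy
myelopathy
dementia
delirium
depression
anxiety
insomnia
apnea
obesity
malnutrition
dehydration
hyponatremia
hypernatremia
hypokalemia
hyperkalemia
hypoglycemia
hyperglycemia
acidosis
alkalosis
hypoxia
dyspnea
orthopnea
hemoptysis
epistaxis
syncope
vertigo
tinnitus
photophobia
diplopia
dysphagia
odynophagia
dysuria
hematuria
proteinuria
melena
hematochezia
jaundice
pruritus
urticaria
erythema
ecchymosis
petechiae
lesion
nodule
cyst
polyp
tumor
mass
biopsy
cytology
histology
radiograph
ultrasound
echocardiogram
electrocardiogram
ekg
ecg
mri
angiogram
endoscopy
colonoscopy
bronchoscopy
catheterization
intubation
ventilation
resuscitation
defibrillation
cardioversion
stent
bypass
graft
amputation
debridement
hemoglobin
hematocrit
platelet
platelets
leukocyte
neutrophil
lymphocyte
creatinine
bun
bilirubin
albumin
globulin
amylase
lipase
troponin
ferritin
transferrin
fibrinogen
inr
ptt
esr
crp
tsh
hba1c
ldl
hdl
triglycerides
cholesterol
electrolytes
bmp
cmp
cbc
wbc
rbc
bid
tid
qid
prn
po
iv
im
subq
npo
stat
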