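# Cardiac and extracardiac abnormality counts in the 63-patient cohort.
group	category	count
Sex	Male	40
Sex	Female	23
Cardiac position	Levocardia	15
Cardiac position	Dextrocardia	35
Cardiac position	Mesocardia	13
Atrial arrangement	Atrial situs inversus	20
Atrial arrangement	Isomerism of right atrial appendages	33
Atrial arrangement	Isomerism of left atrial appendages	7
Spleen	Polysplenia	6
Spleen	Asplenia	29
Spleen	Single right spleen	21
Spleen	Single left spleen	7
Bronchi	Bilateral right bronchi (short)	34
Bronchi	Bilateral left bronchi (long)	7
Bronchi	Bronchial inversus	22
Aortic arch	Left aortic arch	17
Aortic arch	Right aortic arch	45
Aortic arch	Aortic arch centrally descending	1
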