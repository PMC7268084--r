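measure	dataset	bac	sen	spec
StructM	Dataset 1	77.26	61.67	92.86
StructM	Dataset 2	60.88	34.67	87.09
StructM	Dataset 3	81.50	63.00	100.00
StructM	Dataset 4	81.25	65.00	97.50
StructM	Dataset 5	74.65	61.11	88.18
GM	Dataset 1	83.45	68.33	98.57
GM	Dataset 2	67.26	40.67	93.85
GM	Dataset 3	81.17	64.00	98.33
GM	Dataset 4	84.17	68.33	100.00
GM	Dataset 5	76.38	56.67	96.09
WM	Dataset 1	73.36	52.62	94.64
WM	Dataset 2	61.59	29.33	93.85
WM	Dataset 3	77.04	55.50	98.57
WM	Dataset 4	77.71	56.67	98.75
WM	Dataset 5	79.92	66.67	93.18
StructM+GM+WM	Dataset 1	87.59	82.14	93.04
StructM+GM+WM	Dataset 2	64.40	35.67	93.13
StructM+GM+WM	Dataset 3	86.92	80.50	93.33
StructM+GM+WM	Dataset 4	86.94	75.00	98.89
StructM+GM+WM	Dataset 5	82.32	80.00	84.64
FuncM	Dataset 1	88.21	79.29	97.14
FuncM	Dataset 2	76.35	55.00	97.69
FuncM	Dataset 3	85.25	70.50	100.00
FuncM	Dataset 4	81.87	65.00	98.75
FuncM	Dataset 5	83.65	71.11	96.18
ReHo	Dataset 1	84.07	68.14	100.00
ReHo	Dataset 2	79.46	62.00	96.92
ReHo	Dataset 3	83.25	66.50	100.00
ReHo	Dataset 4	82.36	65.83	98.89
ReHo	Dataset 5	81.78	65.56	98.00
ALFF	Dataset 1	86.90	73.81	100.00
ALFF	Dataset 2	78.62	63.33	93.90
ALFF	Dataset 3	82.92	67.50	98.33
ALFF	Dataset 4	86.25	72.50	100.00
ALFF	Dataset 5	80.32	65.56	95.09
FuncM+ReHo+ALFF	Dataset 1	92.14	88.57	95.71
FuncM+ReHo+ALFF	Dataset 2	78.93	64.67	93.19
FuncM+ReHo+ALFF	Dataset 3	87.64	81.00	94.29
FuncM+ReHo+ALFF	Dataset 4	90.28	84.17	96.39
FuncM+ReHo+ALFF	Dataset 5	88.97	86.67	91.27
AllCombined	Dataset 1	95.71	94.29	97.14
AllCombined	Dataset 2	79.74	63.33	96.15
AllCombined	Dataset 3	94.29	90.00	98.57
AllCombined	Dataset 4	92.92	85.83	100.00
AllCombined	Dataset 5	91.50	90.00	93.00
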