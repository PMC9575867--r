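keyword,category,country
women,gender,all
woman,gender,all
men,gender,all
man,gender,all
girls,gender,all
boys,gender,all
mothers,gender,all
fathers,gender,all
transgender,gender,all
nonbinary,gender,all
gender equality,gender,all
lgbtq,gender,all
maternal,gender,all
paternity,gender,all
widows,gender,all
daughters,gender,all
sons,gender,all
her majesty,gender,all
businesswomen,gender,all
businessmen,gender,all
children,age,all
child,age,all
kids,age,all
toddlers,age,all
infants,age,all
newborns,age,all
teenagers,age,all
adolescents,age,all
youth,age,all
young people,age,all
students,age,all
adults,age,all
elderly,age,all
seniors,age,all
senior citizens,age,all
retirees,age,all
pensioners,age,all
older adults,age,all
grandparents,age,all
minors,age,all
indigenous,culture,all
first nations,culture,all
aboriginal,culture,all
francophone,culture,all
anglophone,culture,all
multicultural,culture,all
multiculturalism,culture,all
heritage,culture,all
traditions,culture,all
faith communities,culture,all
muslims,culture,all
christians,culture,all
jewish,culture,all
hindus,culture,all
sikhs,culture,all
buddhists,culture,all
ramadan,culture,all
diwali,culture,all
christmas,culture,all
eid,culture,all
immigrants,ethnicity,all
migrants,ethnicity,all
refugees,ethnicity,all
newcomers,ethnicity,all
minorities,ethnicity,all
ethnic minorities,ethnicity,all
racialized,ethnicity,all
diaspora,ethnicity,all
asylum seekers,ethnicity,all
foreign workers,ethnicity,all
expatriates,ethnicity,all
latino,ethnicity,all
hispanic,ethnicity,all
asian,ethnicity,all
african,ethnicity,all
arab,ethnicity,all
kurdish,ethnicity,all
roma,ethnicity,all
inuit,ethnicity,all
metis,ethnicity,all
nurses,employment,all
doctors,employment,all
physicians,employment,all
paramedics,employment,all
pharmacists,employment,all
healthcare workers,employment,all
frontline workers,employment,all
essential workers,employment,all
teachers,employment,all
farmers,employment,all
fishers,employment,all
drivers,employment,all
small businesses,employment,all
entrepreneurs,employment,all
factory workers,employment,all
construction workers,employment,all
hospitality workers,employment,all
retail workers,employment,all
caregivers,employment,all
veterans,employment,all
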