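%
1	achievement
2	benevolence
3	conformity
4	hedonism
5	power
6	security
7	self-direction
8	stimulation
9	tradition
10	universalism
%
accomplish*	1
achieve*	1
adventur*	8
ambiti*	1
ancestor*	9
appropriate*	3
authorit*	5
autonomous*	7
autonomy*	7
bold*	8
boss*	5
capable	1
care	2
cared	2
cares	2
caring	2
certainty	6
choice*	7
choos*	7
chose	7
clean*	6
comfort*	4
command*	5
compassion*	2
competent*	1
complian*	3
comply*	3
control*	5
courtesy	3
creat*	7
curio*	7
custom	9
customary	9
customs	9
dare*	8
daring	8
defence	6
defend*	6
defense	6
delicious*	4
delight*	4
devoted	2
devout*	9
discipline*	3
diversity	10
domina*	5
duties	3
dutiful*	3
duty	3
earn*	1
effort*	1
elders	9
elite*	5
enjoy*	4
environment*	10
equal*	10
excel*	1
excit*	8
explor*	7
fairness	10
faith*	9
forgiv*	2
free	7
freedom*	7
friend*	2
fun	4
generous*	2
gentle*	2
goal*	1
gratif*	4
guard*	6
harmony*	10
health*	6
help*	2
heritage*	9
holy	9
honest*	2
humanity	10
humble*	9
humility	9
improve*	1
inclusive*	10
independen*	7
indulg*	4
influen*	5
injustice	10
insur*	6
intense*	8
invent*	7
justice	10
kind	2
kindness	2
leisure*	4
liberty	7
loyal*	2
luxur*	4
manners	3
master*	1
modest*	9
money	5
natural	10
nature	10
new	8
newest	8
norm	3
norms	3
novel	8
novelty	8
nurtur*	2
obedien*	3
obey*	3
order	6
orderly	6
original*	7
own	7
parties	4
party	4
peace*	10
planet*	10
pleasure*	4
polite*	3
power*	5
pray*	9
prestige*	5
pride	1
progress*	1
proper*	3
protect*	6
proud	1
rank	5
ranking	5
relax*	4
reliab*	6
religio*	9
respect*	3
restrain*	3
rich	5
richer	5
riches	5
rights	10
risk*	8
ritual*	9
rule	3
rules	3
sacred*	9
safe*	6
satisfy*	4
secur*	6
self	7
shelter*	6
skill*	1
stability	6
stable	6
status	5
stimulat*	8
succeed*	1
success*	1
superior*	5
support*	2
surprise*	8
surprising	8
tasty	4
thoughtful*	2
thrill*	8
tolera*	10
tradition*	9
treat	4
treats	4
unity	10
warm*	2
wealth*	5
welfare	10
wild	8
win	1
winner*	1
winning	1
world	10
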