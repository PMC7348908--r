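# Curated list of common English words. Noun phrases of length one that
# appear in this list are dropped during normalization (they carry no
# domain-specific information). Curated in-repo; versioned with the package.
ability
able
access
account
act
action
activity
actual
addition
address
adult
advance
advantage
advice
affect
afternoon
age
agency
agreement
air
airport
alternative
amount
analysis
animal
answer
anything
apartment
appearance
application
approach
area
argument
arm
army
arrival
art
article
aspect
assignment
assistance
association
assumption
atmosphere
attempt
attention
attitude
audience
author
authority
average
award
baby
back
background
balance
ball
bank
base
basis
basket
bath
bathroom
battle
beach
bear
beauty
bed
bedroom
beer
beginning
behavior
being
belief
benefit
bird
birth
birthday
bit
block
blood
board
boat
body
bonus
book
border
boss
bottle
bottom
box
boy
brain
branch
bread
break
breakfast
breath
bridge
brother
budget
building
bus
business
button
buyer
cabinet
cake
camera
camp
campaign
cancer
candidate
cap
capital
car
card
care
career
case
cash
cat
category
cause
celebration
cell
center
chain
chair
challenge
chance
change
channel
chapter
character
charge
charity
chart
check
cheek
chemistry
chest
chicken
child
childhood
choice
church
circle
city
claim
class
classroom
client
climate
clothes
cloud
club
coach
coast
coffee
cold
collection
college
color
combination
comfort
command
comment
commission
committee
communication
community
company
comparison
competition
complaint
computer
concept
concern
conclusion
condition
conference
confidence
conflict
confusion
connection
consequence
consideration
construction
contact
content
contest
context
contract
contribution
control
conversation
cookie
copy
corner
cost
count
country
county
couple
courage
course
court
cousin
cover
craft
credit
crew
crime
criticism
culture
cup
currency
current
customer
cycle
dad
damage
data
database
date
daughter
day
dealer
death
debate
debt
decision
definition
degree
delivery
demand
department
departure
depression
depth
description
design
desire
desk
detail
development
device
diamond
difference
difficulty
dinner
direction
director
dirt
disaster
discipline
discussion
disease
dish
distance
distribution
district
document
dog
door
dot
doubt
draft
drama
drawing
dream
dress
drink
drive
driver
drop
drug
ear
earth
east
economics
economy
edge
editor
education
effect
efficiency
effort
egg
election
element
emotion
emphasis
employee
employer
employment
end
energy
engine
engineering
entertainment
enthusiasm
entrance
entry
environment
equipment
error
establishment
estate
event
evidence
exam
examination
example
exchange
excitement
excuse
exercise
exit
experience
expert
explanation
expression
extent
eye
face
fact
factor
failure
fall
family
fan
farm
farmer
fat
father
fault
fear
feature
feedback
feeling
female
field
fight
figure
file
fill
film
final
finance
finding
finger
fire
fish
fishing
flight
floor
flow
flower
focus
food
foot
football
force
form
fortune
foundation
frame
freedom
friend
friendship
front
fruit
fuel
fun
function
funeral
future
gain
game
gap
garage
garden
gas
gate
gear
gene
general
gift
girl
girlfriend
glass
goal
gold
golf
government
grade
grandmother
grass
ground
group
growth
guarantee
guard
guess
guest
guidance
guide
guitar
guy
habit
hair
half
hall
hand
handle
hat
head
health
hearing
heart
heat
height
hello
help
hide
highway
hill
historian
history
hole
holiday
home
homework
honey
hope
horror
horse
hospital
host
hotel
hour
house
housing
idea
image
imagination
impact
importance
impression
improvement
incident
income
increase
independence
indication
individual
industry
inflation
influence
information
initiative
injury
insect
inside
inspection
inspector
instance
instruction
insurance
intention
interaction
interest
internet
introduction
investment
issue
item
job
judgment
juice
kid
kind
king
kitchen
knee
knife
knowledge
lab
lack
ladder
lady
lake
land
landscape
language
law
lawyer
leader
leadership
league
leg
length
lesson
letter
level
library
life
lift
light
limit
line
link
list
literature
loan
location
lock
log
look
loss
love
luck
lunch
machine
magazine
mail
main
maintenance
majority
male
mall
man
management
manager
manner
manufacturer
map
March
March
marketing
marriage
match
material
math
matter
meal
meaning
measurement
meat
media
medicine
medium
meeting
member
membership
memory
mention
menu
message
metal
method
middle
midnight
milk
mind
minute
mirror
mission
mistake
mixture
mode
model
mom
moment
money
monitor
month
mood
morning
mother
motor
mountain
mouse
mouth
move
movie
mud
muscle
music
nation
nature
neck
need
negotiation
nerve
network
news
newspaper
night
nobody
noise
north
nose
note
nothing
notice
novel
number
nurse
object
objective
obligation
occasion
offer
office
officer
oil
operation
opinion
opportunity
opposite
option
orange
order
organization
outcome
outside
oven
owner
package
page
pain
painting
pair
paper
parent
park
part
particular
partner
party
passage
passenger
passion
past
path
patience
patient
pattern
pause
payment
peace
pen
penalty
people
percentage
perception
performance
period
permission
person
personality
perspective
phase
philosophy
phone
photo
phrase
physics
piano
picture
pie
piece
pin
pipe
pitch
pizza
place
plan
plane
plant
plastic
plate
platform
play
player
pleasure
plenty
poem
poet
poetry
point
police
policy
politics
pollution
pool
population
position
possession
possibility
post
pot
potato
potential
power
practice
preference
preparation
presence
present
presentation
president
pressure
price
pride
priority
problem
procedure
process
produce
product
profession
professor
profile
profit
program
progress
project
promise
promotion
proof
property
proposal
protection
psychology
public
purpose
quality
quantity
quarter
queen
question
quote
race
radio
rain
range
rate
ratio
reaction
reading
reality
reason
reception
recipe
recognition
recommendation
record
recording
reference
reflection
refrigerator
region
relation
relationship
relative
release
relief
remote
rent
repair
replacement
reply
report
republic
reputation
request
requirement
research
reserve
resident
resolution
resource
respect
response
responsibility
rest
restaurant
result
return
revenue
review
revolution
reward
rice
ring
rise
risk
river
road
rock
role
roof
room
rope
rule
run
safety
salad
salary
sale
sample
sand
satisfaction
scale
scene
schedule
scheme
school
science
score
screen
sea
search
season
seat
second
secret
secretary
section
sector
security
selection
self
sense
sentence
series
service
session
setting
shape
share
shelter
shift
shirt
shoe
shop
shopping
shoulder
show
side
sign
signal
signature
significance
silver
singer
sister
site
situation
size
skill
skin
sky
sleep
slice
smoke
snow
society
software
soil
solution
son
song
sort
sound
soup
source
south
space
speaker
speech
speed
spirit
sport
spot
spray
spring
square
stage
standard
star
start
state
statement
station
status
steak
step
stock
stomach
storage
store
storm
story
strategy
street
strength
stress
string
structure
student
studio
study
stuff
style
subject
success
sugar
suggestion
summer
sun
supermarket
support
surgery
surprise
survey
suspect
system
table
tale
talk
tank
target
task
taste
tax
tea
teacher
team
technology
telephone
television
temperature
tendency
tennis
tension
term
test
text
thanks
theme
theory
thing
thought
throat
time
tip
title
today
tomorrow
tone
tongue
tool
tooth
top
topic
total
touch
tour
tourist
towel
tower
town
track
trade
tradition
traffic
training
transition
transportation
trash
travel
treatment
tree
trick
trip
truck
trust
truth
turn
type
understanding
union
unit
university
upstairs
usage
use
user
vacation
value
variation
variety
vegetable
vehicle
version
video
view
village
visit
voice
volume
wall
war
warning
watch
water
way
weakness
wealth
weather
web
website
wedding
week
weekend
weight
welcome
west
wife
win
wind
window
wine
winner
winter
woman
wood
word
work
worker
world
worth
writer
writing
year
youth
zone
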